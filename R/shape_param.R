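#' Lung shape objects
#'
#' A `lung_shape` is the fixed-length point representation used by the shape
#' model: `Z` slices (30 after resampling), each described by `3*(N-1)` points
#' split into three arcs that run between the three per-slice landmarks
#' (A = top, B = bottom-left, C = bottom-right), traversed A->B->C->A with
#' each landmark included as the first point of its arc. Stored as a tibble
#' with columns `slice`, `point`, `arc` (1 = A->B, 2 = B->C, 3 = C->A),
#' `x`, `y`, `z` (mm), plus attributes `n_between` (N), `n_slices` and `side`.
#'
#' The flattened coordinate vector (slice-major, `x1, y1, z1, x2, ...`) is the
#' representation all shape-model algebra works on; [shape_to_vec()] and
#' [vec_to_shape()] convert between the two.
#'
#' @param df tibble with columns `slice`, `point`, `arc`, `x`, `y`, `z`.
#' @param n_between N, the per-arc point count parameter.
#' @param side `"left"` or `"right"`.
#' @return a `lung_shape` tibble.
#' @export
new_lung_shape <- function(df, n_between, side = "right") {
  df <- dplyr::arrange(tibble::as_tibble(df), .data$slice, .data$point)
  n_slices <- length(unique(df$slice))
  per_slice <- 3L * (n_between - 1L)
  if (nrow(df) != per_slice * n_slices)
    stop("lung_shape must have exactly 3*(N-1) points per slice: expected ",
         per_slice * n_slices, ", got ", nrow(df))
  zo <- df$z[!duplicated(df$slice)]
  if (is.unsorted(zo)) stop("slices must be ordered by increasing z")
  structure(df,
            n_between = n_between, n_slices = n_slices, side = side,
            class = c("lung_shape", class(tibble::tibble())))
}

#' @rdname new_lung_shape
#' @param shape a `lung_shape`.
#' @export
shape_to_vec <- function(shape) {
  as.numeric(t(as.matrix(shape[, c("x", "y", "z")])))
}

#' @rdname new_lung_shape
#' @param v numeric vector of length `3 * nrow(template)`.
#' @param template a `lung_shape` providing the index structure.
#' @export
vec_to_shape <- function(v, template) {
  m <- matrix(v, ncol = 3, byrow = TRUE)
  template$x <- m[, 1]
  template$y <- m[, 2]
  template$z <- m[, 3]
  template
}

shape_points_matrix <- function(shape) as.matrix(shape[, c("x", "y", "z")])

#' Locate the three per-slice landmarks on a contour
#'
#' Landmarks are contour extrema: A (top) is the most superior vertex; B
#' (bottom-left) and C (bottom-right) are the laterally extreme vertices of
#' the contour half below the vertex centroid. Ties break to the lowest point
#' index, making the choice deterministic.
#'
#' @param contour tibble for one slice with columns `point`, `x_mm`, `y_mm`
#'   (ordered closed polygon, first point not repeated).
#' @return named integer vector with row positions `top`, `bottom_left`,
#'   `bottom_right` (1-based positions in the contour order).
#' @export
find_landmarks <- function(contour) {
  n <- nrow(contour)
  if (n < 3L) stop("degenerate contour: fewer than 3 points")
  x <- contour$x_mm
  y <- contour$y_mm
  top <- which(y == max(y))[1]
  lower <- which(y < mean(y))
  if (length(lower) < 2L) lower <- setdiff(order(y)[1:max(2L, n - 1L)], top)
  bl <- lower[which(x[lower] == min(x[lower]))[1]]
  br <- lower[which(x[lower] == max(x[lower]))[1]]
  if (bl == br) { # extremely narrow contour: fall back to the two lowest points
    ord <- lower[order(y[lower], lower)]
    bl <- ord[1]
    br <- setdiff(ord, bl)[1]
  }
  if (anyDuplicated(c(top, bl, br)))
    stop("degenerate landmark placement: landmarks not distinct")
  c(top = top, bottom_left = bl, bottom_right = br)
}

#' Resample a slice contour to 3*(N-1) pseudo-landmarks
#'
#' Each landmark-to-landmark arc (A->B, B->C, C->A along the contour) is
#' replaced by `N-1` points equally spaced by arc length, the first of which
#' is the arc's starting landmark. The traversal direction is chosen so that
#' B is reached before C when walking from A.
#'
#' @param contour one-slice contour tibble (`x_mm`, `y_mm`, ordered ring).
#' @param landmarks output of [find_landmarks()] for this contour.
#' @param n_between N (>= 2).
#' @return tibble with columns `point`, `arc`, `x_mm`, `y_mm`.
#' @export
resample_contour <- function(contour, landmarks, n_between = 20) {
  if (n_between < 2L) stop("n_between must be >= 2")
  p <- cbind(contour$x_mm, contour$y_mm)
  n <- nrow(p)
  a <- landmarks[["top"]]
  # rotate ring to start at A
  ring <- ((seq_len(n) + a - 2L) %% n) + 1L
  p <- p[ring, , drop = FALSE]
  pos <- match(c(landmarks[["bottom_left"]], landmarks[["bottom_right"]]), ring)
  if (pos[1] > pos[2]) { # walk the other way so that B precedes C
    p <- p[c(1L, n:2L), , drop = FALSE]
    pos <- n + 2L - pos
  }
  cuts <- c(1L, pos[1], pos[2], n + 1L) # arc k spans rows cuts[k] .. cuts[k+1]
  out <- vector("list", 3L)
  for (k in 1:3) {
    rows <- cuts[k]:cuts[k + 1L]
    rows[rows > n] <- rows[rows > n] - n
    arc <- p[rows, , drop = FALSE]
    seg <- sqrt(rowSums(diff(arc)^2))
    len <- sum(seg)
    if (len <= 0) stop("zero-length arc between landmarks (degenerate placement)")
    s <- c(0, cumsum(seg))
    # N-1 samples: the starting landmark plus equal steps of len/(N-1);
    # the end landmark belongs to the next arc
    target <- len * (0:(n_between - 2L)) / (n_between - 1L)
    keep <- !duplicated(s)
    out[[k]] <- cbind(
      stats::approx(s[keep], arc[keep, 1], xout = target)$y,
      stats::approx(s[keep], arc[keep, 2], xout = target)$y
    )
  }
  m <- do.call(rbind, out)
  tibble::tibble(
    point = seq_len(nrow(m)),
    arc = rep(1:3, each = n_between - 1L),
    x_mm = m[, 1], y_mm = m[, 2]
  )
}

#' Resample a stack of corresponded slices onto a fixed number of z-planes
#'
#' Corresponding points in adjacent slices are joined by straight lines, and
#' new points are interpolated where those lines intersect `target_slices`
#' equally spaced z-planes spanning the shape's own `[z_min, z_max]`. An
#' input that is already `target_slices` equally spaced planes is returned
#' unchanged up to numerical precision (the operation is idempotent).
#'
#' @param per_slice tibble with columns `z_mm`, `point`, `arc`, `x_mm`,
#'   `y_mm`; every slice must carry the same `3*(N-1)` points in the same
#'   order.
#' @param n_between N.
#' @param target_slices number of output planes (default 30).
#' @param side `"left"` or `"right"`.
#' @return a `lung_shape` with `n_slices = target_slices`.
#' @export
resample_slices <- function(per_slice, n_between, target_slices = 30, side = "right") {
  zs <- sort(unique(per_slice$z_mm))
  if (length(zs) < 2L) stop("need at least 2 input slices")
  per_point <- 3L * (n_between - 1L)
  counts <- table(per_slice$z_mm)
  if (any(counts != per_point))
    stop("inconsistent point counts across slices (expected ", per_point,
         " per slice)")
  per_slice <- dplyr::arrange(per_slice, .data$z_mm, .data$point)
  X <- matrix(per_slice$x_mm, nrow = per_point)
  Y <- matrix(per_slice$y_mm, nrow = per_point)
  zt <- seq(zs[1], zs[length(zs)], length.out = target_slices)
  xi <- t(apply(X, 1, function(r) stats::approx(zs, r, xout = zt)$y))
  yi <- t(apply(Y, 1, function(r) stats::approx(zs, r, xout = zt)$y))
  df <- tibble::tibble(
    slice = rep(seq_len(target_slices), each = per_point),
    point = rep(seq_len(per_point), times = target_slices),
    arc = rep(rep(1:3, each = n_between - 1L), times = target_slices),
    x = as.numeric(xi[cbind(
      rep(seq_len(per_point), times = target_slices),
      rep(seq_len(target_slices), each = per_point))]),
    y = as.numeric(yi[cbind(
      rep(seq_len(per_point), times = target_slices),
      rep(seq_len(target_slices), each = per_point))]),
    z = rep(zt, each = per_point)
  )
  new_lung_shape(df, n_between = n_between, side = side)
}

#' Parameterize CT slice contours as a lung shape
#'
#' Runs landmark detection and arc-length resampling on every slice contour,
#' then resamples the stack onto `target_slices` planes.
#'
#' @param contours contour tibble from [extract_slice_contours()].
#' @param n_between N, points per arc (default 20, giving 57 points per slice).
#' @param target_slices output plane count (default 30).
#' @param side `"left"` or `"right"`.
#' @return a `lung_shape`.
#' @export
contours_to_shape <- function(contours, n_between = 20, target_slices = 30,
                              side = "right") {
  slices <- split(contours, contours$z_index)
  per <- purrr::map_dfr(slices, function(sl) {
    lm <- find_landmarks(sl)
    rs <- resample_contour(sl, lm, n_between)
    rs$z_mm <- sl$z_mm[1]
    rs
  })
  resample_slices(per, n_between = n_between, target_slices = target_slices,
                  side = side)
}

#' Analytic volume of a lung shape (ml)
#'
#' Sum of per-slice polygon areas (shoelace) times the inter-plane spacing;
#' used to match the model's scale to a binary target volume.
#'
#' @param shape a `lung_shape`.
#' @return volume in ml.
#' @export
shape_volume_ml <- function(shape) {
  slices <- split(shape, shape$slice)
  zs <- vapply(slices, function(sl) mean(sl$z), numeric(1))  # slice centers
  dz <- if (length(zs) > 1) mean(diff(sort(zs))) else 1
  areas <- vapply(slices, function(sl) {
    abs(shoelace_area(sl$x, sl$y))
  }, numeric(1))
  sum(areas) * dz / 1000
}

#' Write or read lung shapes as CSV
#'
#' Columns `side`, `slice`, `point`, `arc`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param shape a `lung_shape`.
#' @param path CSV file path.
#' @return `path` (write) or a `lung_shape` (read).
#' @export
write_shape_csv <- function(shape, path) {
  df <- tibble::tibble(
    side = attr(shape, "side"), slice = shape$slice, point = shape$point,
    arc = shape$arc, x_mm = shape$x, y_mm = shape$y, z_mm = shape$z
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @export
read_shape_csv <- function(path) {
  df <- utils::read.csv(path)
  per_point <- sum(df$slice == df$slice[1])
  new_lung_shape(
    tibble::tibble(slice = df$slice, point = df$point, arc = df$arc,
                   x = df$x_mm, y = df$y_mm, z = df$z_mm),
    n_between = per_point / 3L + 1L, side = df$side[1]
  )
}
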