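#' CT reference lung segmentation
#'
#' Semi-automated extraction of left/right lung masks from a CT volume:
#' Hounsfield-unit thresholding, removal of ambient air (components touching
#' the volume border), selection of the two largest coherent low-attenuation
#' components, then binary morphology (3D closing, per-slice hole filling) to
#' remove vessel holes. The result is used both to build the shape-model
#' training set and as the reference standard for validation.
#'
#' @param ct an `image_volume` with modality CT (Hounsfield units).
#' @param hu_threshold voxels strictly below this HU count as air-like;
#'   default -320 HU separates aerated lung (about -800 HU) from soft tissue
#'   (about +40 HU).
#' @return a list with elements `left` and `right`, each a binary
#'   `image_volume` mask. "Left" is the patient's left (larger `x` centroid).
#' @export
segment_ct_lungs <- function(ct, hu_threshold = -320) {
  stopifnot(inherits(ct, "image_volume"))
  air <- ct$voxels < hu_threshold
  labs <- label_components_3d(air)
  if (max(labs) > 0) {
    border <- border_labels(labs)
    if (length(border)) labs[labs %in% border] <- 0L
  }
  sizes <- tabulate(labs[labs > 0L])
  if (length(sizes) < 2L || sort(sizes, decreasing = TRUE)[2] < 1)
    stop("lungs not found: fewer than two interior low-HU components below ",
         hu_threshold, " HU")
  keep <- order(sizes, decreasing = TRUE)[1:2]
  comp <- lapply(keep, function(l) {
    m <- labs == l
    m <- binary_closing_3d(m, radius = 1L)
    m <- fill_holes_slicewise(m)
    largest_component(m)
  })
  # overlapping voxels (possible after closing) go to the nearer centroid
  ov <- comp[[1]] & comp[[2]]
  if (any(ov)) {
    cen <- lapply(comp, mask_centroid_idx)
    w <- which(ov, arr.ind = TRUE)
    d1 <- rowSums(sweep(w, 2, cen[[1]])^2)
    d2 <- rowSums(sweep(w, 2, cen[[2]])^2)
    comp[[1]][w[d1 > d2, , drop = FALSE]] <- FALSE
    comp[[2]][w[d1 <= d2, , drop = FALSE]] <- FALSE
  }
  cx <- vapply(comp, function(m) mask_centroid_idx(m)[1], numeric(1))
  left <- comp[[which.max(cx)]]   # x increases toward the patient's left
  right <- comp[[which.min(cx)]]
  as_mask <- function(m) image_volume(array(as.numeric(m), dim(ct$voxels)),
                                      ct$spacing, ct$origin, "MASK")
  list(left = as_mask(left), right = as_mask(right))
}

#' Extract ordered closed contours from a binary mask, slice by slice
#'
#' One closed polygon per coronal (constant-`z`) slice that intersects the
#' mask, traced along the 0.5 iso-contour of the zero-padded slice, oriented
#' counter-clockwise in the (x, y) plane, with vertices in physical mm.
#' Slices with several components keep the largest (by enclosed area) with a
#' warning; empty slices are omitted.
#'
#' @param mask a binary `image_volume`.
#' @return a tibble with columns `z_index`, `z_mm`, `point`, `x_mm`, `y_mm`,
#'   `edited` (all `FALSE` here; see [manual_edit_hook()]).
#' @export
extract_slice_contours <- function(mask) {
  stopifnot(inherits(mask, "image_volume"))
  if (!is_binary_mask(mask)) stop("mask values must all be 0 or 1")
  d <- dim(mask$voxels)
  xs <- axis_mm(mask, 1)
  ys <- axis_mm(mask, 2)
  # pad one voxel so border-touching masks still yield closed contours
  xpad <- c(xs[1] - mask$spacing[1], xs, xs[d[1]] + mask$spacing[1])
  ypad <- c(ys[1] - mask$spacing[2], ys, ys[d[2]] + mask$spacing[2])
  zs <- axis_mm(mask, 3)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- mask$voxels[, , k]
    if (!any(sl > 0)) next
    padded <- matrix(0, d[1] + 2L, d[2] + 2L)
    padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- sl
    cl <- grDevices::contourLines(xpad, ypad, padded, levels = 0.5)
    if (length(cl) == 0L) next
    if (length(cl) > 1L) {
      areas <- vapply(cl, function(p) abs(shoelace_area(p$x, p$y)), numeric(1))
      warning("slice ", k, ": ", length(cl),
              " contour components, keeping the largest", call. = FALSE)
      cl <- cl[which.max(areas)]
    }
    px <- cl[[1]]$x
    py <- cl[[1]]$y
    n <- length(px)
    if (n > 1L && px[1] == px[n] && py[1] == py[n]) {
      px <- px[-n]; py <- py[-n]
    }
    if (shoelace_area(px, py) < 0) {  # enforce counter-clockwise
      px <- rev(px); py <- rev(py)
    }
    out[[k]] <- tibble::tibble(
      z_index = k, z_mm = zs[k], point = seq_along(px),
      x_mm = px, y_mm = py, edited = FALSE
    )
  }
  dplyr::bind_rows(out)
}

#' Apply manual contour corrections
#'
#' Replaces whole slice polygons (the analog of an observer removing vessels
#' or cardiac structures from individual slices). Replaced slices carry
#' `edited = TRUE`.
#'
#' @param contours a contour tibble from [extract_slice_contours()].
#' @param edits a list of edits, each a list with `z_index` and `polygon`
#'   (an n x 2 matrix of (x_mm, y_mm) vertices, open ring, n >= 3).
#' @return the edited contour tibble.
#' @export
manual_edit_hook <- function(contours, edits) {
  if (length(edits) == 0L) return(contours)
  for (e in edits) {
    zi <- e$z_index
    if (!zi %in% contours$z_index)
      stop("edit references slice ", zi, " which has no contour")
    poly <- e$polygon
    if (is.null(dim(poly)) || nrow(poly) < 3L)
      stop("replacement polygon for slice ", zi, " needs at least 3 points")
    zmm <- contours$z_mm[match(zi, contours$z_index)]
    contours <- dplyr::bind_rows(
      dplyr::filter(contours, .data$z_index != zi),
      tibble::tibble(z_index = zi, z_mm = zmm, point = seq_len(nrow(poly)),
                     x_mm = poly[, 1], y_mm = poly[, 2], edited = TRUE)
    )
  }
  dplyr::arrange(contours, .data$z_index, .data$point)
}

#' Rasterize slice contours back to a binary mask
#'
#' Voxel centers inside (or on) each slice polygon are set to 1 on the grid
#' of `ref`. Grid planes without a contour stay empty.
#'
#' @param contours contour tibble (columns `z_index`, `x_mm`, `y_mm`).
#' @param ref an `image_volume` defining the output grid.
#' @return a binary `image_volume` mask.
#' @export
rasterize_contours <- function(contours, ref) {
  d <- dim(ref$voxels)
  out <- array(0, d)
  xs <- axis_mm(ref, 1)
  ys <- axis_mm(ref, 2)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  for (zi in unique(contours$z_index)) {
    poly <- as.matrix(contours[contours$z_index == zi, c("x_mm", "y_mm")])
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
    out[, , zi] <- out[, , zi] + matrix(as.numeric(inside), d[1], d[2])
  }
  out[out > 1] <- 1
  image_volume(out, ref$spacing, ref$origin, "MASK")
}

#' Export or import contours as CSV
#'
#' Plain-text interchange: columns `side`, `z_index`, `point`, `x_mm`,
#' `y_mm`, `z_mm`, `edited`.
#'
#' @param contours contour tibble; may carry a `side` column.
#' @param path CSV path.
#' @return `path` (write) or the contour tibble (read).
#' @export
write_contours_csv <- function(contours, path) {
  utils::write.csv(contours, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

# --- low-level binary image machinery --------------------------------------

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# 3D connected components: EBImage 2D labeling per slice, then union-find
# across adjacent slices (6-connectivity in z).
label_components_3d <- function(arr) {
  d <- dim(arr)
  labs <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    if (!any(sl)) next
    l2 <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(sl), d[1], d[2]))),
                 d[1], d[2])
    pos <- l2 > 0L
    l2[pos] <- l2[pos] + offset
    offset <- max(l2)
    labs[, , k] <- l2
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(d[3] - 1L)) {
    a <- labs[, , k]
    b <- labs[, , k + 1L]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    pairs <- unique(cbind(a[sel], b[sel]))
    for (i in seq_len(nrow(pairs))) {
      ra <- find_root(pairs[i, 1]); rb <- find_root(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- labs > 0L
  labs[pos] <- relab[labs[pos]]
  labs
}

border_labels <- function(labs) {
  d <- dim(labs)
  faces <- c(
    labs[1, , ], labs[d[1], , ],
    labs[, 1, ], labs[, d[2], ],
    labs[, , 1], labs[, , d[3]]
  )
  unique(faces[faces > 0L])
}

largest_component <- function(mask) {
  labs <- label_components_3d(mask)
  if (max(labs) <= 1L) return(mask)
  sizes <- tabulate(labs[labs > 0L])
  labs == which.max(sizes)
}

mask_centroid_idx <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colMeans(w)
}

shift_array <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  xs_to <- intersect(sx + dx, sx); xs_from <- xs_to - dx
  ys_to <- intersect(sy + dy, sy); ys_from <- ys_to - dy
  zs_to <- intersect(sz + dz, sz); zs_from <- zs_to - dz
  out <- array(fill, d)
  out[xs_to, ys_to, zs_to] <- a[xs_from, ys_from, zs_from]
  out
}

neighbor_offsets6 <- rbind(
  c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
)

binary_dilate_3d <- function(mask, radius = 1L) {
  for (r in seq_len(radius)) {
    acc <- mask
    for (i in seq_len(nrow(neighbor_offsets6))) {
      o <- neighbor_offsets6[i, ]
      acc <- acc | shift_array(mask, o[1], o[2], o[3], fill = FALSE)
    }
    mask <- acc
  }
  mask
}

binary_erode_3d <- function(mask, radius = 1L) {
  for (r in seq_len(radius)) {
    acc <- mask
    for (i in seq_len(nrow(neighbor_offsets6))) {
      o <- neighbor_offsets6[i, ]
      acc <- acc & shift_array(mask, o[1], o[2], o[3], fill = FALSE)
    }
    mask <- acc
  }
  mask
}

binary_closing_3d <- function(mask, radius = 1L) {
  binary_erode_3d(binary_dilate_3d(mask, radius), radius)
}

fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    filled <- EBImage::fillHull(matrix(as.numeric(sl), d[1], d[2]))
    out[, , k] <- as.numeric(filled) > 0
  }
  out
}
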