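#' Build the normalized ventilation + perfusion sum image
#'
#' Each input volume is normalized by its own maximum intensity, then the two
#' are summed voxelwise; the result ranges over [0, 2] and peaks where both
#' tracers are high. Segmentation is performed on this sum so that a defect
#' in only one of the two studies still leaves boundary signal.
#'
#' @param vent,perf `image_volume`s on the same grid with positive maxima.
#' @return an `image_volume` (modality `SUM`) with attributes `norm_vent` and
#'   `norm_perf`, the normalization constants.
#' @export
make_sum_image <- function(vent, perf) {
  stopifnot(inherits(vent, "image_volume"), inherits(perf, "image_volume"))
  if (!identical(dim(vent$voxels), dim(perf$voxels)) ||
      !isTRUE(all.equal(vent$spacing, perf$spacing)) ||
      !isTRUE(all.equal(vent$origin, perf$origin)))
    stop("ventilation and perfusion volumes are on different grids")
  mv <- max(vent$voxels)
  mp <- max(perf$voxels)
  if (mv <= 0) stop("ventilation volume has no positive intensities")
  if (mp <= 0) stop("perfusion volume has no positive intensities")
  out <- image_volume(vent$voxels / mv + perf$voxels / mp,
                      vent$spacing, vent$origin, "SUM")
  attr(out, "norm_vent") <- mv
  attr(out, "norm_perf") <- mp
  out
}

#' Binary initialization of the lung region
#'
#' A low threshold — `frac` (default 15%) of the maximum intensity of the sum
#' image — extracts a binary lung volume. This deliberately overestimates the
#' lungs but provides the centroid, the upper/lower z-limits and the volume
#' used to place the mean shape. The volume is split into left and right
#' halves at the sagittal plane through the valley of the mask's left-right
#' marginal profile.
#'
#' @param sum_img the sum `image_volume`.
#' @param frac threshold fraction of the maximum (default 0.15).
#' @return list with `mask` (binary `image_volume`), `centroid_mm`,
#'   `z_range_mm`, `volume_ml`, `threshold` (absolute intensity) and `split`
#'   (list of binary `image_volume`s `left`, `right`).
#' @export
binary_init <- function(sum_img, frac = 0.15) {
  stopifnot(inherits(sum_img, "image_volume"))
  thr <- frac * max(sum_img$voxels)
  m <- sum_img$voxels >= thr
  if (!any(m)) stop("empty mask at threshold ", signif(thr, 4))
  w <- which(m, arr.ind = TRUE)
  centroid <- colMeans(index_to_mm(sum_img, w))
  zs <- axis_mm(sum_img, 3)
  z_range <- range(zs[unique(w[, 3])])
  vol_ml <- nrow(w) * prod(sum_img$spacing) / 1000
  # sagittal split at the valley of the left-right marginal count profile:
  # locate the two dominant local maxima of the lightly smoothed profile
  # (robust when a matched defect weakens one lung) and take the minimum
  # between them
  prof <- apply(m, 1, sum)
  sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  n_x <- length(sm)
  is_peak <- vapply(seq_len(n_x), function(i) {
    sm[i] > 0 &&
      sm[i] >= max(sm[max(1, i - 2):min(n_x, i + 2)])
  }, logical(1))
  peaks <- which(is_peak)
  # keep peaks at least 4 columns apart, strongest first
  peaks <- peaks[order(-sm[peaks])]
  sel <- integer()
  for (p in peaks) if (all(abs(p - sel) >= 4)) sel <- c(sel, p)
  if (length(sel) >= 2) {
    two <- sort(sel[1:2])
    between <- seq(two[1], two[2])
    valley <- between[which.min(sm[between])]
  } else {
    com <- sum(seq_along(prof) * prof) / sum(prof)
    valley <- round(com)
  }
  right_m <- m
  if (valley < dim(m)[1])
    right_m[(valley + 1):dim(m)[1], , ] <- FALSE  # lower x: patient right
  left_m <- m & !right_m
  as_mask <- function(a) image_volume(array(as.numeric(a), dim(m)),
                                      sum_img$spacing, sum_img$origin, "MASK")
  list(mask = as_mask(m), centroid_mm = centroid, z_range_mm = z_range,
       volume_ml = vol_ml, threshold = thr,
       split = list(left = as_mask(left_m), right = as_mask(right_m)))
}

# principal axes of a point cloud with deterministic sign convention:
# each eigenvector's largest-magnitude component is made positive, and the
# third axis is flipped if needed so the frame is right-handed.
principal_frame <- function(pts) {
  E <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
  for (j in 1:2) {
    k <- which.max(abs(E[, j]))
    if (E[k, j] < 0) E[, j] <- -E[, j]
  }
  # third axis completes a right-handed frame, so the sign convention of the
  # first two axes fully determines the orientation
  E[, 3] <- c(E[2, 1] * E[3, 2] - E[3, 1] * E[2, 2],
              E[3, 1] * E[1, 2] - E[1, 1] * E[3, 2],
              E[1, 1] * E[2, 2] - E[2, 1] * E[1, 2])
  E
}

#' Place the mean shape in the image from the binary initialization
#'
#' The model mean is scaled so that its enclosed volume matches the side's
#' binary volume, rotated so its principal axes match the principal axes of
#' the side's binary mask (the SVD alignment reduces to this axis match for
#' the mask, which carries no point correspondence), and translated so the
#' centroids coincide.
#'
#' @param model an `asm_model`.
#' @param init output of [binary_init()].
#' @param side `"left"` or `"right"`.
#' @return list with `shape` (a `lung_shape` in the image frame) and `pose`
#'   (list `s`, `R`, `t` mapping model frame to image frame,
#'   `x_img = s * x_model %*% t(R) + t`).
#' @export
place_mean_shape <- function(model, init, side = model$side) {
  mask <- init$split[[side]]
  nvox <- sum(mask$voxels)
  if (nvox == 0) stop("empty ", side, " mask: nothing to initialize from")
  if (nvox < 2) stop("degenerate ", side, " mask (single voxel)")
  target_ml <- nvox * prod(mask$spacing) / 1000
  mean_shape <- generate_shape(model, numeric(model$t))
  Xc <- center_shape(mean_shape)
  X <- Xc$X
  v0 <- shape_volume_ml(vec_to_shape(as.numeric(t(X)),
                                     make_shape_template(model$n_between,
                                                         model$n_slices,
                                                         model$side)))
  s <- (target_ml / v0)^(1 / 3)
  w <- which(mask$voxels > 0, arr.ind = TRUE)
  pts <- index_to_mm(mask, w)
  R <- principal_frame(pts) %*% t(principal_frame(X))
  tr <- colMeans(pts)
  Ximg <- s * X %*% t(R) + matrix(tr, nrow(X), 3, byrow = TRUE)
  shape <- vec_to_shape(as.numeric(t(Ximg)),
                        make_shape_template(model$n_between, model$n_slices,
                                            model$side))
  list(shape = shape, pose = list(s = s, R = R, t = tr))
}

# outward surface normals at every shape point: cross product of the
# in-slice tangent (neighboring ring points) and the across-slice tangent
# (corresponding points in the slices above/below), sign-fixed to point away
# from the slice centroid.
shape_normals <- function(shape) {
  P <- shape_points_matrix(shape)
  n_sl <- attr(shape, "n_slices")
  pp <- nrow(P) / n_sl
  idx <- matrix(seq_len(nrow(P)), nrow = pp)   # [point, slice]
  nxt <- idx[c(2:pp, 1), , drop = FALSE]
  prv <- idx[c(pp, 1:(pp - 1)), , drop = FALSE]
  up <- idx[, c(2:n_sl, n_sl), drop = FALSE]   # one-sided at the ends
  dn <- idx[, c(1, 1:(n_sl - 1)), drop = FALSE]
  t1 <- P[as.vector(nxt), ] - P[as.vector(prv), ]
  t2 <- P[as.vector(up), ] - P[as.vector(dn), ]
  nrm <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
               t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
               t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
  len <- sqrt(rowSums(nrm^2))
  # fall back to the in-plane radial direction where the cross product degenerates
  cen <- rowsum(P, rep(seq_len(n_sl), each = pp)) / pp
  rad <- P - cen[rep(seq_len(n_sl), each = pp), , drop = FALSE]
  bad <- len < 1e-9
  if (any(bad)) {
    rl <- sqrt(rowSums(rad^2))
    nrm[bad, ] <- rad[bad, ] / pmax(rl[bad], 1e-9)
    len[bad] <- 1
  }
  nrm <- nrm / len
  flip <- rowSums(nrm * rad) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

#' One boundary-update pass along intensity profiles
#'
#' For every shape point, the sum image (rescaled to [0, 1] by its own
#' maximum) is sampled along the outward surface normal over
#' `c(-profile_len, profile_len)` mm at `step` mm spacing (trilinear
#' interpolation; out-of-field samples clamp to the border). The candidate
#' position is the minimum of the finite-difference derivative — the
#' steepest intensity falloff. Two rules override the profile search to
#' avoid local minima: (a) if the intensity at the current point exceeds
#' 0.30, the point moves outward by one step; (b) if it is below 0.05, the
#' point moves inward by one step (this shrinks contours that reached
#' outside the lungs). Otherwise the point moves to the candidate.
#'
#' @param shape a `lung_shape` in the image frame.
#' @param sum_img the sum `image_volume` (any positive scale; rescaled
#'   internally).
#' @param profile_len half-length of the search profile in mm (default 5
#'   voxels of the in-plane spacing).
#' @param step sample spacing along the profile in mm (default half a voxel).
#' @param hi,lo override thresholds on the [0, 1] intensity scale
#'   (defaults 0.30 and 0.05).
#' @return the updated `lung_shape`.
#' @export
update_contour <- function(shape, sum_img,
                           profile_len = 5 * sum_img$spacing[1],
                           step = sum_img$spacing[1] / 2,
                           hi = 0.30, lo = 0.05) {
  P <- shape_points_matrix(shape)
  n <- nrow(P)
  nrm <- shape_normals(shape)
  offs <- seq(-profile_len, profile_len, by = step)
  k <- length(offs)
  pts <- P[rep(seq_len(n), each = k), ] +
    nrm[rep(seq_len(n), each = k), ] * rep(offs, times = n)
  vals <- sample_trilinear(sum_img, pts) / max(sum_img$voxels)
  vals <- matrix(vals, nrow = k)                 # [offset, point]
  deriv <- (vals[c(2:k, k), ] - vals[c(1, 1:(k - 1)), ]) / (2 * step)
  cand <- offs[max.col(t(-deriv), ties.method = "first")]
  i0 <- which.min(abs(offs))                     # offset 0 sample
  cur <- vals[i0, ]
  move <- ifelse(cur > hi, step, ifelse(cur < lo, -step, cand))
  newP <- P + nrm * move
  # clamp to the physical extent of the grid
  lo_mm <- sum_img$origin
  hi_mm <- sum_img$origin + (dim(sum_img$voxels) - 1) * sum_img$spacing
  for (a in 1:3) newP[, a] <- pmin(pmax(newP[, a], lo_mm[a]), hi_mm[a])
  vec_to_shape(as.numeric(t(newP)), shape)
}

#' Constrain a shape to the model's plausible range
#'
#' The shape is pose-aligned to the model mean (centered, scaled to unit
#' Frobenius size, rotated by the SVD rule), projected onto the eigenvector
#' basis (`b = t(P) %*% (x - mean)`), and each coefficient is clipped to the
#' plausibility box before the shape is reconstructed and mapped back to the
#' image frame by the inverse pose.
#'
#' The default box is the literal `[-lambda_i * sqrt(2), lambda_i * sqrt(2)]`
#' on the eigenvalue itself (`b_limit = "paper"`); `b_limit = "classic"`
#' uses the conventional `[-3 * sqrt(lambda_i), 3 * sqrt(lambda_i)]` (three
#' standard deviations). The literal box is far tighter, so the fit leans
#' heavily on the mean shape; see the package vignette.
#'
#' @param model an `asm_model`.
#' @param shape a `lung_shape` in the image frame.
#' @param b_limit `"paper"` or `"classic"`.
#' @return list with `shape` (constrained, image frame), `b` (clipped
#'   coefficients), `b_raw` (before clipping), `pose` and `clipped` (logical
#'   vector).
#' @export
constrain_shape <- function(model, shape, b_limit = c("paper", "classic")) {
  b_limit <- match.arg(b_limit)
  X <- shape_points_matrix(shape)
  if (nrow(X) * 3 != length(model$mean))
    stop("shape has ", nrow(X), " points but the model expects ",
         length(model$mean) / 3)
  cen <- colMeans(X)
  Xc <- sweep(X, 2, cen)
  s <- frobenius_volume(Xc)
  Xu <- Xc / s
  mean_mat <- matrix(model$mean, ncol = 3, byrow = TRUE)
  al <- align_rotation(Xu, mean_mat)
  b_raw <- project_shape(model, al$X)
  lim <- switch(b_limit, paper = model$eigenvalues * sqrt(2),
                classic = 3 * sqrt(model$eigenvalues))
  b <- pmin(pmax(b_raw, -lim), lim)
  rec <- model$mean + if (model$t > 0) as.numeric(model$P %*% b) else 0
  Xm <- matrix(rec, ncol = 3, byrow = TRUE)
  Ximg <- s * (Xm %*% al$R) + matrix(cen, nrow(Xm), 3, byrow = TRUE)
  list(shape = vec_to_shape(as.numeric(t(Ximg)), shape),
       b = b, b_raw = b_raw, clipped = b != b_raw,
       pose = list(s = s, R = al$R, t = cen))
}

#' Rasterize a lung shape to a binary mask
#'
#' Per-slice polygon scan fill on the grid of `ref`: every grid z-plane
#' within half a shape-slice gap of the shape's z-range takes the polygon of
#' the nearest shape slice; voxel centers inside or on the polygon become 1.
#'
#' @param shape a `lung_shape` in the image frame.
#' @param ref `image_volume` defining the output grid.
#' @return a binary `image_volume` mask.
#' @export
rasterize_shape <- function(shape, ref) {
  d <- dim(ref$voxels)
  out <- array(0, d)
  zs_grid <- axis_mm(ref, 3)
  xs <- axis_mm(ref, 1)
  ys <- axis_mm(ref, 2)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  slices <- split(shape, shape$slice)
  slice_z <- vapply(slices, function(sl) mean(sl$z), numeric(1))
  dz <- if (length(slice_z) > 1) mean(diff(sort(slice_z))) else ref$spacing[3]
  for (k in seq_len(d[3])) {
    z <- zs_grid[k]
    if (z < min(slice_z) - dz / 2 || z > max(slice_z) + dz / 2) next
    sl <- slices[[which.min(abs(slice_z - z))]]
    poly <- cbind(sl$x, sl$y)
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
    out[, , k] <- matrix(as.numeric(inside), d[1], d[2])
  }
  image_volume(out, ref$spacing, ref$origin, "MASK")
}

fit_one_side <- function(model, init, sum_img, side, n_iter, profile_len,
                         step, hi, lo, b_limit) {
  placed <- place_mean_shape(model, init, side)
  shape <- placed$shape
  b <- numeric(model$t)
  trace <- tibble::tibble(iteration = integer(), mean_disp_mm = numeric(),
                          max_abs_b_ratio = numeric())
  vox <- mean(sum_img$spacing[1:2])
  if (n_iter > 0) {
    lim <- switch(b_limit, paper = model$eigenvalues * sqrt(2),
                  classic = 3 * sqrt(model$eigenvalues))
    for (i in seq_len(n_iter)) {
      before <- shape_points_matrix(shape)
      upd <- update_contour(shape, sum_img, profile_len = profile_len,
                            step = step, hi = hi, lo = lo)
      con <- constrain_shape(model, upd, b_limit = b_limit)
      stopifnot(all(abs(con$b) <= lim + 1e-12))
      shape <- con$shape
      b <- con$b
      disp <- mean(sqrt(rowSums((shape_points_matrix(shape) - before)^2)))
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        iteration = i, mean_disp_mm = disp,
        max_abs_b_ratio = if (model$t > 0) max(abs(con$b) / lim) else 0
      ))
    }
    pose <- con$pose
  } else {
    pose <- placed$pose
  }
  mask <- rasterize_shape(shape, sum_img)
  structure(
    list(side = side, shape = shape, pose = pose, b = b, mask = mask,
         trace = trace, n_iter = n_iter,
         volume_ml = sum(mask$voxels) * prod(mask$spacing) / 1000,
         voxel_mm = vox),
    class = "asm_fit"
  )
}

#' Segment a V/P SPECT study with trained shape models
#'
#' The full automatic pipeline: sum image, 15%-of-maximum binary
#' initialization, mean-shape placement per side, then a fixed number of
#' iterations (default 10, found sufficient for convergence) alternating a
#' boundary update along intensity profiles with the shape-plausibility
#' constraint. The left and right lungs are fitted by independent models;
#' failure of one side is reported as a diagnostic while the other side is
#' still returned.
#'
#' @param vent,perf co-registered ventilation and perfusion `image_volume`s.
#' @param model_left,model_right `asm_model`s for the two lungs.
#' @param n_iter update/constrain iterations (default 10).
#' @param binary_frac initialization threshold fraction (default 0.15).
#' @param profile_len,step profile geometry in mm; defaults are 5 voxels and
#'   half a voxel of the SPECT in-plane spacing.
#' @param hi,lo override-rule thresholds (defaults 0.30, 0.05).
#' @param b_limit plausibility box, `"paper"` or `"classic"`.
#' @return an object of class `asm_segmentation`: list with `left`, `right`
#'   (each an `asm_fit` or an error condition), `sum_image`, `init`.
#' @export
segment_study <- function(vent, perf, model_left, model_right, n_iter = 10,
                          binary_frac = 0.15,
                          profile_len = NULL, step = NULL,
                          hi = 0.30, lo = 0.05,
                          b_limit = c("paper", "classic")) {
  b_limit <- match.arg(b_limit)
  sum_img <- make_sum_image(vent, perf)
  if (is.null(profile_len)) profile_len <- 5 * sum_img$spacing[1]
  if (is.null(step)) step <- sum_img$spacing[1] / 2
  init <- binary_init(sum_img, frac = binary_frac)
  fits <- list()
  for (side in c("left", "right")) {
    model <- if (side == "left") model_left else model_right
    fits[[side]] <- tryCatch(
      fit_one_side(model, init, sum_img, side, n_iter, profile_len, step,
                   hi, lo, b_limit),
      error = function(e) {
        warning(side, " lung fit failed: ", conditionMessage(e), call. = FALSE)
        e
      }
    )
  }
  structure(list(left = fits$left, right = fits$right,
                 sum_image = sum_img, init = init),
            class = "asm_segmentation")
}

#' @export
print.asm_segmentation <- function(x, ...) {
  cat("<asm_segmentation>\n")
  for (side in c("left", "right")) {
    f <- x[[side]]
    if (inherits(f, "asm_fit")) {
      cat(sprintf("  %s: %.0f ml after %d iterations (final mean step %.2f mm)\n",
                  side, f$volume_ml, f$n_iter,
                  if (nrow(f$trace)) f$trace$mean_disp_mm[nrow(f$trace)] else NA))
    } else {
      cat(sprintf("  %s: FAILED (%s)\n", side, conditionMessage(f)))
    }
  }
  invisible(x)
}

#' Tidy the iteration trace of a fitted segmentation
#'
#' @param x an `asm_segmentation`.
#' @param ... unused.
#' @return tibble with `side`, `iteration`, `mean_disp_mm`, `mean_disp_voxel`,
#'   `max_abs_b_ratio`.
#' @export
tidy.asm_segmentation <- function(x, ...) {
  purrr::map_dfr(c("left", "right"), function(side) {
    f <- x[[side]]
    if (!inherits(f, "asm_fit")) return(tibble::tibble())
    dplyr::mutate(f$trace, side = side,
                  mean_disp_voxel = .data$mean_disp_mm / f$voxel_mm,
                  .before = 1)
  })
}

#' One-row-per-side summary of a fitted segmentation
#'
#' @param x an `asm_segmentation`.
#' @param ... unused.
#' @return tibble with `side`, `ok`, `volume_ml`, `n_iter`, `final_disp_mm`.
#' @export
glance.asm_segmentation <- function(x, ...) {
  purrr::map_dfr(c("left", "right"), function(side) {
    f <- x[[side]]
    if (!inherits(f, "asm_fit"))
      return(tibble::tibble(side = side, ok = FALSE, volume_ml = NA_real_,
                            n_iter = NA_integer_, final_disp_mm = NA_real_))
    tibble::tibble(side = side, ok = TRUE, volume_ml = f$volume_ml,
                   n_iter = f$n_iter,
                   final_disp_mm = if (nrow(f$trace))
                     f$trace$mean_disp_mm[nrow(f$trace)] else NA_real_)
  })
}
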