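# a boxy "lung" shape for rule-level tests: ellipse cross-sections stacked
# along z, expressed as a lung_shape
box_shape <- function(n_between = 6, n_slices = 10, rx = 30, ry = 40,
                      cx = 0, cy = 0, z0 = -40, z1 = 40) {
  pp <- 3 * (n_between - 1)
  th <- seq(pi / 2, pi / 2 + 2 * pi, length.out = pp + 1)[-(pp + 1)]
  zs <- seq(z0, z1, length.out = n_slices)
  df <- tibble::tibble(
    slice = rep(seq_len(n_slices), each = pp),
    point = rep(seq_len(pp), times = n_slices),
    arc = rep(rep(1:3, each = n_between - 1), times = n_slices),
    x = rep(cx + rx * cos(th), times = n_slices),
    y = rep(cy + ry * sin(th), times = n_slices),
    z = rep(zs, each = pp)
  )
  new_lung_shape(df, n_between = n_between, side = "right")
}

flat_volume <- function(value, max_value = 1, d = c(40, 40, 20),
                        spacing = c(5, 5, 5)) {
  org <- -(d - 1) * spacing / 2
  vox <- array(value, d)
  vox[1, 1, 1] <- max_value   # pins the normalization away from the shape
  image_volume(vox, spacing, org, "SUM")
}

test_that("sum image is the sum of the max-normalized inputs", {
  cs <- small_case(seed = 17)
  s <- make_sum_image(cs$vent, cs$vent)
  expect_equal(max(s$voxels), 2)
  expect_equal(s$voxels, 2 * cs$vent$voxels / max(cs$vent$voxels))
  zero <- image_volume(array(0, dim(cs$vent$voxels)), cs$vent$spacing,
                       cs$vent$origin, "SPECT-P")
  expect_error(make_sum_image(cs$vent, zero), "positive")
  other <- image_volume(cs$perf$voxels[1:10, 1:10, 1:10], cs$perf$spacing,
                        cs$perf$origin, "SPECT-P")
  expect_error(make_sum_image(cs$vent, other), "grid")
  # noiseless phantom: co-located hottest voxel gives sum max exactly 2
  cs0 <- small_case(seed = 17, noise = FALSE)
  s0 <- make_sum_image(cs0$vent, cs0$perf)
  expect_equal(max(s0$voxels), 2, tolerance = 1e-12)
})

test_that("binary initialization thresholds at exactly 15% of the maximum", {
  d <- c(10, 10, 5)
  vox <- array(seq(0, 1, length.out = prod(d)), d)
  vol <- image_volume(vox, c(6.8, 6.8, 6.8), -(d - 1) * 6.8 / 2, "SUM")
  init <- binary_init(vol)
  expect_equal(init$threshold, 0.15 * max(vox))
  expect_equal(init$mask$voxels, array(as.numeric(vox >= 0.15 * max(vox)), d))
  # a uniform image exceeds the threshold everywhere (documented overestimate)
  u <- image_volume(array(1, d), c(1, 1, 1), modality = "SUM")
  expect_equal(sum(binary_init(u)$mask$voxels), prod(d))
  # fraction is configurable
  expect_equal(binary_init(vol, frac = 0.5)$threshold, 0.5 * max(vox))
})

test_that("binary initialization overestimates and splits the two lungs", {
  cs <- small_case(seed = 17)
  s <- make_sum_image(cs$vent, cs$perf)
  init <- binary_init(s)
  truth_ml <- mask_volume_ml(cs$truth_spect$left) +
    mask_volume_ml(cs$truth_spect$right)
  expect_gte(init$volume_ml, truth_ml)
  for (side in c("left", "right")) {
    cen <- colMeans(index_to_mm(cs$truth_spect[[side]],
                                which(cs$truth_spect[[side]]$voxels > 0,
                                      arr.ind = TRUE)))
    idx <- round(mm_to_index(init$split[[side]], rbind(cen)))
    expect_equal(init$split[[side]]$voxels[idx[1], idx[2], idx[3]], 1,
                 label = side)
  }
  # z-limits bracket the lungs
  wz <- which(apply(cs$truth_spect$left$voxels +
                    cs$truth_spect$right$voxels, 3, sum) > 0)
  zmm <- axis_mm(s, 3)[wz]
  expect_lte(init$z_range_mm[1], min(zmm))
  expect_gte(init$z_range_mm[2], max(zmm))
})

test_that("mean-shape placement recovers pose from its own rasterization", {
  # distinct extents per axis so the principal axes are unambiguous, and
  # small enough that the 1.5x-scaled copy still fits the grid
  shp <- box_shape(rx = 22, ry = 32, z0 = -40, z1 = 40)
  vol <- image_volume(array(0, c(40, 40, 30)), c(5, 5, 5),
                      -(c(40, 40, 30) - 1) * 5 / 2, "SUM")
  mask <- rasterize_shape(shp, vol)
  # a fake single-mode model whose mean is the (unit-scaled) box shape
  cs <- center_shape(shp)
  U <- cs$X / frobenius_volume(cs$X)
  model <- structure(list(
    mean = as.numeric(t(U)), P = matrix(0, length(U), 0), eigenvalues = numeric(),
    all_eigenvalues = numeric(), t = 0L, variance_fraction = 1, m = 2L,
    n_between = attr(shp, "n_between"), n_slices = attr(shp, "n_slices"),
    side = "right", schema_version = "spectasm-model-1"), class = "asm_model")
  init <- list(split = list(right = mask))
  pl <- place_mean_shape(model, init, "right")
  s_true <- frobenius_volume(cs$X)
  expect_lt(abs(pl$pose$s - s_true) / s_true, 0.02)
  ang <- acos(pmin(1, (sum(diag(pl$pose$R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 2)
  expect_lt(max(abs(pl$pose$t - cs$centroid)), 5)  # within one voxel
  # scaled mask recovers the scale
  shp2 <- vec_to_shape(as.numeric(t(1.5 * (shape_points_matrix(shp) -
    matrix(cs$centroid, nrow(cs$X), 3, byrow = TRUE)))), shp)
  mask2 <- rasterize_shape(shp2, vol)
  pl2 <- place_mean_shape(model, list(split = list(right = mask2)), "right")
  expect_lt(abs(pl2$pose$s - 1.5 * s_true) / (1.5 * s_true), 0.05)
  empty <- image_volume(array(0, dim(mask$voxels)), mask$spacing, mask$origin,
                        "MASK")
  expect_error(place_mean_shape(model, list(split = list(right = empty)),
                                "right"), "empty")
})

test_that("override rules fire exactly at the 0.30 and 0.05 thresholds", {
  shp <- box_shape()
  step <- 2.5
  # plateau at 0.5 of max: rule (a) moves every point outward one step
  hi_vol <- flat_volume(0.5, max_value = 1)
  out <- update_contour(shp, hi_vol, profile_len = 25, step = step)
  d <- sqrt(rowSums((shape_points_matrix(out) - shape_points_matrix(shp))^2))
  expect_equal(d, rep(step, length(d)), tolerance = 1e-9)
  expect_gte(shape_volume_ml(out), shape_volume_ml(shp))
  # background at 0.02 of max: rule (b) moves every point inward one step
  lo_vol <- flat_volume(0.02, max_value = 1)
  out <- update_contour(shp, lo_vol, profile_len = 25, step = step)
  d <- sqrt(rowSums((shape_points_matrix(out) - shape_points_matrix(shp))^2))
  expect_equal(d, rep(step, length(d)), tolerance = 1e-9)
  expect_lte(shape_volume_ml(out), shape_volume_ml(shp))
  # exactly at the thresholds neither override fires (strict inequalities):
  # intensities 0.30 and 0.05 on a flat profile leave the derivative flat, so
  # the candidate rule applies instead of a fixed one-step move
  for (v in c(0.30, 0.05)) {
    vol <- flat_volume(v, max_value = 1)
    out <- update_contour(shp, vol, profile_len = 25, step = step)
    d <- sqrt(rowSums((shape_points_matrix(out) - shape_points_matrix(shp))^2))
    # flat derivative -> candidate at the profile start, not +/- one step
    expect_false(isTRUE(all.equal(d, rep(step, length(d)))), label = v)
  }
  # just above/below: overrides fire again
  vol <- flat_volume(0.300001, max_value = 1)
  out <- update_contour(shp, vol, profile_len = 25, step = step)
  expect_gte(shape_volume_ml(out), shape_volume_ml(shp))
  vol <- flat_volume(0.049999, max_value = 1)
  out <- update_contour(shp, vol, profile_len = 25, step = step)
  expect_lte(shape_volume_ml(out), shape_volume_ml(shp))
})

test_that("the profile search lands on a step edge when no override fires", {
  # dim cylinder (0.25 of max, inside the override-free band) with a sharp
  # wall at r = 45: the steepest falloff along the outward normal sits at
  # the wall, so points at r = 38 should move there
  d <- c(60, 60, 30); spacing <- c(2.5, 2.5, 5)
  org <- -(d - 1) * spacing / 2
  pts <- expand.grid(x = org[1] + (0:59) * 2.5, y = org[2] + (0:59) * 2.5,
                     z = org[3] + (0:29) * 5)
  r <- sqrt(pts$x^2 + pts$y^2)
  vox <- array(0.25 * (r < 45), d)
  vox[1, 1, 1] <- 1   # pins the normalization: point intensity stays 0.25
  vol <- image_volume(vox, spacing, org, "SUM")
  shp <- box_shape(rx = 38, ry = 38, z0 = -30, z1 = 30)
  out <- update_contour(shp, vol, profile_len = 12.5, step = 1.25)
  rad <- sqrt(out$x^2 + out$y^2)
  mid <- out$slice %in% 3:8
  expect_lt(max(abs(rad[mid] - 45)), 2 * 1.25 + max(spacing[1:2]))
})

test_that("the plausibility constraint clips b to +/- lambda*sqrt(2)", {
  set.seed(33)
  shapes <- lapply(1:10, function(i) {
    s <- box_shape(rx = 30 + rnorm(1, sd = 2), ry = 40 + rnorm(1, sd = 2))
    shape_points_matrix(s)
  })
  al <- procrustes_align(shapes)
  proj <- lapply(al$aligned, tangent_project, mean_shape = al$mean)
  model <- fit_pca(proj, variance_fraction = 0.95)
  model$n_between <- 6L; model$n_slices <- 10L
  lam1 <- model$eigenvalues[1]
  mean_shape <- generate_shape(model, numeric(model$t))
  # shape = mean: b = 0, unchanged up to numerics
  con <- constrain_shape(model, mean_shape)
  expect_equal(con$b, numeric(model$t) * 0, tolerance = 1e-10)
  expect_equal(shape_points_matrix(con$shape), shape_points_matrix(mean_shape),
               tolerance = 1e-7)
  # shape = mean + 5*lambda1*sqrt(2) along mode 1: clipped to the bound exactly
  b_big <- numeric(model$t); b_big[1] <- 5 * lam1 * sqrt(2)
  far <- generate_shape(model, b_big)
  con <- constrain_shape(model, far)
  expect_equal(con$b[1], lam1 * sqrt(2), tolerance = 1e-12)
  expect_true(con$clipped[1])
  # shape = mean + 0.5*lambda1*sqrt(2): kept as is
  b_half <- numeric(model$t); b_half[1] <- 0.5 * lam1 * sqrt(2)
  near <- generate_shape(model, b_half)
  con <- constrain_shape(model, near)
  expect_equal(con$b[1], 0.5 * lam1 * sqrt(2), tolerance = 1e-5)
  expect_false(any(con$clipped))
  # classic limit is wider: the same far shape is not clipped at 3*sqrt(lambda)
  con_c <- constrain_shape(model, far, b_limit = "classic")
  expect_false(con_c$clipped[1])
  expect_error(constrain_shape(model, box_shape(n_between = 4)), "points")
})

test_that("the fitting loop runs the fixed number of iterations", {
  cs <- small_case(seed = 17)
  spec <- cs$spec
  shapes <- lapply(1:5, function(i) {
    surf <- list(left = sample_lung_geometry(spec, "left", seed = 400 + i),
                 right = sample_lung_geometry(spec, "right", seed = 500 + i))
    truth <- render_truth(surf, spec, "ct")
    list(left = contours_to_shape(
           suppressWarnings(extract_slice_contours(truth$left)),
           n_between = 10, side = "left"),
         right = contours_to_shape(
           suppressWarnings(extract_slice_contours(truth$right)),
           n_between = 10, side = "right"))
  })
  ml <- train_shape_model(lapply(shapes, `[[`, "left"))
  mr <- train_shape_model(lapply(shapes, `[[`, "right"))
  fit <- segment_study(cs$vent, cs$perf, ml, mr)
  expect_equal(nrow(fit$left$trace), 10)
  expect_equal(nrow(fit$right$trace), 10)
  expect_true(all(tidy(fit)$max_abs_b_ratio <= 1 + 1e-12))
  # n_iter = 0 returns the placed mean shape
  fit0 <- segment_study(cs$vent, cs$perf, ml, mr, n_iter = 0)
  expect_equal(nrow(fit0$left$trace), 0)
  b0 <- fit0$right$b
  expect_equal(b0, numeric(mr$t))
  # determinism: identical inputs give bit-identical masks
  fit2 <- segment_study(cs$vent, cs$perf, ml, mr)
  expect_identical(fit$left$mask$voxels, fit2$left$mask$voxels)
  expect_identical(fit$right$b, fit2$right$b)
  # the two sides come from independent models
  expect_gt(sum(abs(shape_points_matrix(fit$left$shape) -
                    shape_points_matrix(fit$right$shape))), 0)
  g <- glance(fit)
  expect_equal(g$side, c("left", "right"))
  expect_true(all(g$ok))
})
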