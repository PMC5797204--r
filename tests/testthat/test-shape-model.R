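test_that("centering and Frobenius size behave as defined", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  cs <- center_shape(X)
  expect_equal(cs$centroid, c(0.5, 0.5, 0.5))
  expect_equal(colMeans(cs$X), c(0, 0, 0), tolerance = 1e-12)
  # idempotence
  expect_equal(center_shape(cs$X)$X, cs$X)
  expect_equal(frobenius_volume(rbind(c(1, 0, 0))), 1)
  expect_equal(frobenius_volume(rbind(c(1, 0, 0), c(-1, 0, 0))), sqrt(2))
  U <- cs$X / frobenius_volume(cs$X)
  expect_equal(frobenius_volume(U), 1)
  expect_error(frobenius_volume(matrix(0, 3, 3)), "degenerate")
})

test_that("SVD alignment recovers known rotations and resists reflections", {
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  X <- center_shape(X)$X; X <- X / frobenius_volume(X)
  expect_equal(align_rotation(X, X)$R, diag(3), tolerance = 1e-10)
  R30 <- euler_rot(az = 30 * pi / 180)
  Y <- X %*% t(R30)
  al <- align_rotation(X, Y)
  expect_equal(al$R, R30, tolerance = 1e-10)
  expect_lt(sum((al$X - Y)^2), 1e-10)
  expect_true(det(al$R) > 0)
  expect_error(align_rotation(X, X[1:5, ]), "mismatch")
})

test_that("SVD alignment beats a 1-degree brute-force Euler grid under noise", {
  set.seed(22)
  X <- matrix(rnorm(30), 10, 3)
  X <- center_shape(X)$X; X <- X / frobenius_volume(X)
  R_true <- euler_rot(ax = 6 * pi / 180, ay = -9 * pi / 180, az = 4 * pi / 180)
  Y <- X %*% t(R_true) + matrix(rnorm(30, sd = 0.01), 10, 3)
  Y <- center_shape(Y)$X
  D_svd <- sum((align_rotation(X, Y)$X - Y)^2)
  D_grid <- brute_force_rotation_D(X, Y, window_deg = 15, step_deg = 1)
  expect_lte(D_svd, D_grid + 1e-12)
})

test_that("Procrustes alignment converges and is rotation invariant", {
  set.seed(23)
  base <- matrix(rnorm(60), 20, 3)
  # copies of one shape under random rotations align almost exactly
  rots <- lapply(1:5, function(i)
    euler_rot(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1)))
  shapes <- lapply(rots, function(R) base %*% t(R))
  al <- procrustes_align(shapes)
  expect_lte(nrow(al$report), 3)
  expect_lt(al$report$D[nrow(al$report)], 1e-8)
  # two identical shapes: D = 0 after the first pass
  al2 <- procrustes_align(list(base, base))
  expect_equal(al2$report$D[1], 0, tolerance = 1e-12)
  # D trace is non-increasing on a noisy population
  shapes3 <- lapply(1:8, function(i)
    (base + matrix(rnorm(60, sd = 0.3), 20, 3)) %*% t(rots[[(i %% 5) + 1]]))
  al3 <- procrustes_align(shapes3, d_stop = 1e-12, max_iter = 10) |>
    suppressWarnings()
  expect_true(all(diff(al3$report$D) <= 1e-9))
  # applying one global rotation to all inputs leaves final D unchanged
  Rg <- euler_rot(0.3, -0.2, 0.5)
  al4 <- suppressWarnings(
    procrustes_align(lapply(shapes3, function(s) s %*% t(Rg)),
                     d_stop = 1e-12, max_iter = 10))
  expect_equal(al3$report$D[nrow(al3$report)], al4$report$D[nrow(al4$report)],
               tolerance = 1e-6)
  expect_error(procrustes_align(list(base)), "at least 2")
})

test_that("tangent projection scales by the reciprocal inner product", {
  set.seed(24)
  mn <- matrix(rnorm(30), 10, 3)
  mn <- center_shape(mn)$X; mn <- mn / frobenius_volume(mn)
  expect_equal(tangent_project(mn, mn), mn, tolerance = 1e-12)
  # X . mean = 0.5  ->  all coordinates double
  X <- 0.5 * mn
  expect_equal(tangent_project(X, mn), mn, tolerance = 1e-12)
  # identity: after projection X' . mean = |mean|^2 (= 1 for the unit mean)
  for (i in 1:5) {
    X <- mn + matrix(rnorm(30, sd = 0.05), 10, 3)
    Xp <- tangent_project(X, mn)
    expect_equal(sum(Xp * mn), sum(mn^2), tolerance = 1e-10)
  }
  expect_error(tangent_project(-mn, mn), "inner product")
})

test_that("PCA recovers planted modes, eigenvalues and round-trips b", {
  set.seed(25)
  n <- 40
  mn <- matrix(rnorm(3 * n), n, 3)
  v <- rnorm(3 * n); v <- v / sqrt(sum(v^2))      # planted unit direction
  b_true <- rnorm(200)
  b_true <- (b_true - mean(b_true)) / stats::sd(b_true) * 3  # exact SD 3
  shapes <- lapply(b_true, function(b) mn + matrix(b * v, n, 3, byrow = FALSE))
  # bypass alignment: feed the planted population straight to PCA
  model <- fit_pca(shapes, variance_fraction = 0.95)
  expect_equal(model$t, 1)
  # retained direction matches the planted one
  v_rowmajor <- as.numeric(t(matrix(v, n, 3)))
  expect_gte(abs(sum(model$P[, 1] * v_rowmajor)), 0.99)
  # eigenvalue equals the 1/m-normalized sample variance of b exactly,
  # and the population variance within 5% for this draw
  expect_equal(model$eigenvalues[1],
               sum((b_true - mean(b_true))^2) / length(b_true),
               tolerance = 1e-8)
  expect_lt(abs(model$eigenvalues[1] - 9) / 9, 0.05)
  # generate/project round-trip recovers b exactly
  b <- sqrt(model$eigenvalues[1])
  gen <- generate_shape(model, b)
  expect_equal(project_shape(model, gen), b, tolerance = 1e-10)
  # displacement collinear with the planted direction
  disp <- as.numeric(t(gen)) - model$mean
  expect_gte(abs(sum(disp * v_rowmajor)) / sqrt(sum(disp^2)), 0.99)
})

test_that("cumulative-variance mode retention keeps both planted modes", {
  set.seed(26)
  n <- 30
  mn <- matrix(0, n, 3)
  v1 <- rnorm(3 * n); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(3 * n); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  shapes <- lapply(1:400, function(i) {
    d <- rnorm(1, sd = 3) * v1 + rnorm(1, sd = 1) * v2
    mn + matrix(d, n, 3, byrow = FALSE)
  })
  model <- fit_pca(shapes, variance_fraction = 0.95)
  # variances 9 and 1: first mode alone is 90% < 95%, so both are kept
  expect_equal(model$t, 2)
  # identical shapes: all eigenvalues 0, t = 0, warned
  expect_warning(m0 <- fit_pca(list(mn, mn, mn)), "degenerate")
  expect_equal(m0$t, 0)
  expect_error(fit_pca(list(mn)), "at least 2")
})

test_that("SVD route equals the explicit covariance eigen-decomposition", {
  set.seed(27)
  shapes <- lapply(1:12, function(i) matrix(rnorm(15), 5, 3))
  model <- fit_pca(shapes, variance_fraction = 1)
  M <- t(vapply(shapes, function(x) as.numeric(t(x)), numeric(15)))
  S <- crossprod(sweep(M, 2, colMeans(M))) / nrow(M)   # 1/m covariance
  ev <- eigen(S, symmetric = TRUE)
  k <- length(model$eigenvalues)
  expect_equal(model$eigenvalues, ev$values[1:k], tolerance = 1e-10)
  for (j in 1:min(3, k))
    expect_gte(abs(sum(model$P[, j] * ev$vectors[, j])), 1 - 1e-8)
})

test_that("with all modes retained, training shapes reconstruct exactly", {
  set.seed(28)
  shapes <- lapply(1:8, function(i) matrix(rnorm(24), 8, 3))
  model <- fit_pca(shapes, variance_fraction = 1)
  for (s in shapes[c(1, 5)]) {
    b <- project_shape(model, s)
    rec <- generate_shape(model, b)
    expect_equal(as.numeric(t(rec)), as.numeric(t(s)), tolerance = 1e-8)
  }
})

test_that("model training on phantom lungs produces orthonormal modes", {
  spec <- small_spec(31)
  shapes <- lapply(1:6, function(i) {
    surf <- sample_lung_geometry(spec, "right", seed = 100 + i)
    truth <- render_truth(list(left = sample_lung_geometry(spec, "left",
                                                           seed = 200 + i),
                               right = surf), spec, "ct")
    contours <- suppressWarnings(extract_slice_contours(truth$right))
    contours_to_shape(contours, n_between = 10, side = "right")
  })
  model <- train_shape_model(shapes)
  G <- crossprod(model$P)
  expect_equal(G, diag(model$t), tolerance = 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_gte(model$variance_fraction, 0.95)
  td <- tidy(model)
  expect_equal(td$b_limit_paper, model$eigenvalues * sqrt(2))
  expect_equal(glance(model)$n_modes, model$t)
})
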