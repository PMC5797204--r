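# Shared fixtures, built in code.

# a small phantom spec on reduced grids: used by unit tests of individual
# operations where full-resolution grids would only add runtime. The
# full-size default spec is exercised by the acceptance suite.
small_spec <- function(seed = 7) {
  phantom_spec(
    seed = seed,
    ct_dim = c(64L, 64L, 36L), ct_spacing = c(6, 6, 8),
    spect_dim = c(48L, 48L, 30L), spect_spacing = c(9, 9, 9)
  )
}

small_case <- function(seed = 7, defects = list(), noise = TRUE) {
  spec <- small_spec(seed)
  surfaces <- list(
    left = sample_lung_geometry(spec, "left", seed = seed),
    right = sample_lung_geometry(spec, "right", seed = seed + 1L)
  )
  ct <- render_ct(surfaces, spec, seed = seed + 11L, noise = noise)
  sp <- render_spect(surfaces, spec, defects = defects, seed = seed + 13L,
                     noise = noise)
  list(spec = spec, surfaces = surfaces, ct = ct$ct, truth_ct = ct$truth,
       vent = sp$vent, perf = sp$perf, truth_spect = sp$truth)
}

# an ordered-ring contour tibble for one slice
ring_contour <- function(x, y, z_index = 1, z_mm = 0) {
  tibble::tibble(z_index = z_index, z_mm = z_mm, point = seq_along(x),
                 x_mm = x, y_mm = y, edited = FALSE)
}

circle_contour <- function(n = 360, r = 50, cx = 0, cy = 0, ...) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # start at angle 0 (3 o\'clock), counter-clockwise
  ring_contour(cx + r * cos(th), cy + r * sin(th), ...)
}

# brute-force rotation search: best rotation from a 1-degree Euler-angle grid
# in a window around the identity (the true rotation must lie inside)
brute_force_rotation_D <- function(X, X_ref, window_deg = 15, step_deg = 1) {
  angs <- seq(-window_deg, window_deg, by = step_deg) * pi / 180
  rot <- function(ax, ay, az) {
    Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
    Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3)
    Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  best <- Inf
  for (ax in angs) for (ay in angs) for (az in angs) {
    R <- rot(ax, ay, az)
    D <- sum((X %*% t(R) - X_ref)^2)
    if (D < best) best <- D
  }
  best
}

euler_rot <- function(ax = 0, ay = 0, az = 0) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}
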