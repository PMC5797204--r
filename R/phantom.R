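#' Digital CT/SPECT lung phantom specification
#'
#' Parameters of the synthetic paired-acquisition generator: a low-dose-CT
#' grid (default 128 x 128 x 60 voxels at 3 x 3 x 5 mm, 5 mm slices) and a
#' SPECT grid (64 x 64 x 40 at 6.8 mm isotropic) sharing one physical frame
#' centered on the origin (the phantom is emitted "co-registered", as from a
#' hybrid scanner); two lung-like bodies built from tapered superellipsoids
#' with a cardiac-notch concavity that bites deeper into the left lung (the
#' heart ellipsoid sits left of the midline); planted statistical modes of
#' variation (global scale, sup-inf stretch, lateral shear, diaphragm
#' height, concavity depth); and imaging noise (additive Gaussian HU noise
#' on CT; Poisson counting noise on SPECT after a Gaussian system-resolution
#' blur of 2 voxels FWHM in-plane).
#'
#' Geometry defaults are chosen so that a default cohort's ground-truth lung
#' volumes fall in the 1000-3500 ml range with the left mean near 1700 ml
#' and the right mean near 2100 ml, the ordering and scale seen in adult
#' reference CT volumes.
#'
#' @param seed master seed; every per-case draw derives from it.
#' @param ct_dim,ct_spacing,spect_dim,spect_spacing grid geometry.
#' @param sd_scale,sd_stretch,sd_shear SDs of the planted multiplicative /
#'   shear deformation modes (dimensionless).
#' @param sd_diaphragm SD of the diaphragm height shift (mm).
#' @param sd_concavity SD of the relative concavity-depth variation.
#' @param ct_noise_hu additive Gaussian CT noise SD (HU).
#' @param vent_peak,perf_peak expected peak counts of the two SPECT studies.
#' @param background_frac SPECT background as a fraction of the plateau.
#' @param gradient_frac apex-to-base linear uptake gradient (apex lower).
#' @param blur_fwhm_voxel Gaussian resolution blur FWHM in SPECT voxels.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1,
                         ct_dim = c(128L, 128L, 60L), ct_spacing = c(3, 3, 5),
                         spect_dim = c(64L, 64L, 40L),
                         spect_spacing = c(6.8, 6.8, 6.8),
                         sd_scale = 0.06, sd_stretch = 0.06, sd_shear = 0.04,
                         sd_diaphragm = 8, sd_concavity = 0.15,
                         ct_noise_hu = 20,
                         vent_peak = 50, perf_peak = 150,
                         background_frac = 0.02, gradient_frac = 0.2,
                         blur_fwhm_voxel = 2) {
  structure(list(
    seed = seed,
    ct_dim = as.integer(ct_dim), ct_spacing = ct_spacing,
    spect_dim = as.integer(spect_dim), spect_spacing = spect_spacing,
    ct_origin = -(as.numeric(ct_dim) - 1) * ct_spacing / 2,
    spect_origin = -(as.numeric(spect_dim) - 1) * spect_spacing / 2,
    # base geometry (mm): semi-axes (a lateral, b sup-inf, c ant-post),
    # lateral center offset, apex taper, sup-inf exponent
    lungs = list(
      right = list(center = c(-57, 0, 0), a = 57, b = 115, c = 84,
                   taper = 0.25, py = 3),
      left = list(center = c(57, 0, 0), a = 54, b = 112, c = 82,
                  taper = 0.25, py = 3)
    ),
    # heart ellipsoid, global frame, left of midline and antero-inferior
    heart = list(center = c(20, -35, -22), semi = c(42, 55, 45)),
    body = list(semi_x = 168, semi_z = 106),
    dome = 12,       # diaphragm dome height (mm)
    septum_mm = 8,   # mediastinal gap: the lungs never touch at the midline
    sd_scale = sd_scale, sd_stretch = sd_stretch, sd_shear = sd_shear,
    sd_diaphragm = sd_diaphragm, sd_concavity = sd_concavity,
    ct_noise_hu = ct_noise_hu, vent_peak = vent_peak, perf_peak = perf_peak,
    background_frac = background_frac, gradient_frac = gradient_frac,
    blur_fwhm_voxel = blur_fwhm_voxel,
    hu = c(outside = -1000, body = 40, lung = -800)
  ), class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

case_seed <- function(spec, index) {
  (abs(spec$seed) * 131L + index * 7919L) %% 2147483629L + 1L
}

#' Draw a randomized analytic lung surface
#'
#' Samples the planted deformation-mode amplitudes for one lung and returns
#' the resulting analytic surface as an implicit-membership object: base
#' superellipsoid with apex taper and diaphragm dome, affine deformation
#' (scale, sup-inf stretch, lateral shear, diaphragm shift), minus the heart
#' ellipsoid (scaled by the concavity draw). With all variability SDs zero,
#' two calls with any seeds give identical surfaces.
#'
#' @param spec a `phantom_spec`.
#' @param side `"left"` or `"right"`.
#' @param seed integer seed for the amplitude draws.
#' @return a `lung_surface`: list of drawn parameters plus `inside(pts_mm)`.
#' @export
sample_lung_geometry <- function(spec, side = c("right", "left"), seed = 1) {
  side <- match.arg(side)
  # mode amplitudes are clamped at +/- 1.5 SD, as when sampling a statistical
  # shape model within its plausibility box: keeps every phantom anatomically
  # credible and the cohort volumes inside the adult reference range
  rdraw <- function(sd) {
    if (sd == 0) return(0)
    max(min(stats::rnorm(1, 0, sd), 1.5 * sd), -1.5 * sd)
  }
  draws <- with_seed(seed, list(
    scale = 1 + rdraw(spec$sd_scale),
    stretch = 1 + rdraw(spec$sd_stretch),
    shear = rdraw(spec$sd_shear),
    diaphragm = rdraw(spec$sd_diaphragm),
    concavity = 1 + rdraw(spec$sd_concavity)
  ))
  geom <- spec$lungs[[side]]
  heart <- spec$heart
  dome <- spec$dome
  septum <- spec$septum_mm %||% 8
  med_sign <- sign(geom$center[1])   # +1 left lung, -1 right lung
  inside <- function(pts) {
    q <- sweep(rbind(pts), 2, geom$center)
    q[, 1] <- (q[, 1] - draws$shear * q[, 2]) / draws$scale
    q[, 3] <- q[, 3] / draws$scale
    q[, 2] <- q[, 2] / (draws$scale * draws$stretch)
    u <- q[, 2] / geom$b
    f <- pmax(1 - geom$taper * ((pmin(pmax(u, -1), 1) + 1) / 2)^2, 0.05)
    r2 <- (q[, 1] / (geom$a * f))^2 + (q[, 3] / (geom$c * f))^2
    core <- r2 + abs(u)^geom$py < 1
    # diaphragm: dome-shaped floor, shifted by the diaphragm draw
    floor_y <- -geom$b + draws$diaphragm + dome * (1 - pmin(r2, 1))
    core <- core & q[, 2] > floor_y
    # cardiac notch, evaluated in the undeformed global frame
    h <- sweep(rbind(pts), 2, heart$center)
    hs <- heart$semi * draws$concavity
    in_heart <- (h[, 1] / hs[1])^2 + (h[, 2] / hs[2])^2 + (h[, 3] / hs[3])^2 < 1
    # mediastinal septum: each lung stays on its own side of the midline
    own_side <- med_sign * rbind(pts)[, 1] > septum / 2
    core & !in_heart & own_side
  }
  structure(list(side = side, draws = draws, geom = geom, inside = inside,
                 seed = seed),
            class = "lung_surface")
}

grid_points <- function(dim, spacing, origin) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  cbind(rep(xs, times = dim[2] * dim[3]),
        rep(rep(ys, each = dim[1]), times = dim[3]),
        rep(zs, each = dim[1] * dim[2]))
}

#' Voxelize the ground-truth masks of a surface pair
#'
#' @param surfaces list with `left`, `right` `lung_surface`s.
#' @param spec a `phantom_spec`.
#' @param grid `"ct"` or `"spect"`.
#' @return list of binary `image_volume`s `left`, `right` (made disjoint:
#'   a voxel claimed by both goes to the nearer lung center).
#' @export
render_truth <- function(surfaces, spec, grid = c("ct", "spect")) {
  grid <- match.arg(grid)
  d <- spec[[paste0(grid, "_dim")]]
  sp <- spec[[paste0(grid, "_spacing")]]
  org <- spec[[paste0(grid, "_origin")]]
  pts <- grid_points(d, sp, org)
  lm <- array(as.numeric(surfaces$left$inside(pts)), d)
  rm_ <- array(as.numeric(surfaces$right$inside(pts)), d)
  both <- lm > 0 & rm_ > 0
  if (any(both)) { # overlapping voxels go to the nearer lung center
    w <- which(both)
    dl <- rowSums(sweep(pts[w, , drop = FALSE], 2, surfaces$left$geom$center)^2)
    dr <- rowSums(sweep(pts[w, , drop = FALSE], 2, surfaces$right$geom$center)^2)
    lm[w[dl > dr]] <- 0
    rm_[w[dl <= dr]] <- 0
  }
  list(left = image_volume(lm, sp, org, "MASK"),
       right = image_volume(rm_, sp, org, "MASK"))
}

#' Render the low-dose CT volume of a surface pair
#'
#' Lung voxels get -800 HU, the body elliptic cylinder +40 HU, surrounding
#' air -1000 HU, plus additive Gaussian noise. The returned truth masks are
#' the exact voxelizations of the surfaces.
#'
#' @param surfaces list with `left`, `right` `lung_surface`s.
#' @param spec a `phantom_spec`.
#' @param seed noise seed.
#' @param noise apply Gaussian noise (default TRUE).
#' @return list with `ct` (`image_volume`) and `truth` (list `left`,
#'   `right`).
#' @export
render_ct <- function(surfaces, spec, seed = 1, noise = TRUE) {
  d <- spec$ct_dim
  pts <- grid_points(d, spec$ct_spacing, spec$ct_origin)
  truth <- render_truth(surfaces, spec, "ct")
  body <- (pts[, 1] / spec$body$semi_x)^2 + (pts[, 3] / spec$body$semi_z)^2 <= 1
  vox <- array(spec$hu[["outside"]], d)
  vox[array(body, d)] <- spec$hu[["body"]]
  vox[truth$left$voxels > 0 | truth$right$voxels > 0] <- spec$hu[["lung"]]
  if (noise && spec$ct_noise_hu > 0) {
    vox <- vox + with_seed(seed, array(stats::rnorm(length(vox), 0,
                                                    spec$ct_noise_hu), d))
  }
  list(ct = image_volume(vox, spec$ct_spacing, spec$ct_origin, "CT"),
       truth = truth)
}

# separable Gaussian blur; sigma per axis in voxels
gaussian_blur_3d <- function(arr, sigma_voxel) {
  d <- dim(arr)
  blur_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    n <- d[axis]
    half <- max(1L, ceiling(3 * sigma))
    kx <- (-half):half
    k <- exp(-kx^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + kx
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- c(axis, setdiff(1:3, axis))
    res <- K %*% matrix(aperm(a, perm), nrow = n)
    aperm(array(res, d[perm]), order(perm))
  }
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma_voxel[min(ax, length(sigma_voxel))])
  arr
}

#' Render the ventilation and perfusion SPECT volumes
#'
#' Uptake is a plateau inside the lungs with a linear apex-to-base gradient
#' (apex `1 - gradient_frac`, base 1), a background at `background_frac` of
#' the plateau, spherical defects multiplying the uptake inside their
#' radius, a Gaussian blur of `blur_fwhm_voxel` FWHM standing in for system
#' resolution, and Poisson counting noise at the study's peak-count scale.
#' Ventilation and perfusion share the (matched) defects but draw
#' independent noise.
#'
#' @param surfaces list with `left`, `right` `lung_surface`s.
#' @param spec a `phantom_spec`.
#' @param defects list of defects, each `list(side, center, radius_mm,
#'   multiplier)` with `center` in mm.
#' @param seed noise seed.
#' @param noise apply Poisson noise (default TRUE).
#' @return list with `vent`, `perf` (`image_volume`s) and `truth`
#'   (SPECT-grid masks `left`, `right`).
#' @export
render_spect <- function(surfaces, spec, defects = list(), seed = 1,
                         noise = TRUE) {
  d <- spec$spect_dim
  pts <- grid_points(d, spec$spect_spacing, spec$spect_origin)
  truth <- render_truth(surfaces, spec, "spect")
  lung <- truth$left$voxels > 0 | truth$right$voxels > 0
  uptake <- array(spec$background_frac, d)
  if (any(lung)) {
    ymm <- pts[, 2][as.vector(lung)]
    yr <- range(ymm)
    grad <- 1 - spec$gradient_frac * (ymm - yr[1]) / max(yr[2] - yr[1], 1)
    uptake[lung] <- grad
  }
  for (df in defects) {
    dist2 <- rowSums(sweep(pts, 2, df$center)^2)
    hit <- array(dist2 < df$radius_mm^2, d) & lung
    if (!any(hit))
      warning("defect at (", paste(round(df$center), collapse = ", "),
              ") does not intersect the lungs", call. = FALSE)
    uptake[hit] <- uptake[hit] * df$multiplier
  }
  sigma <- spec$blur_fwhm_voxel / (2 * sqrt(2 * log(2)))
  uptake <- gaussian_blur_3d(uptake, rep(sigma, 3))
  make_study <- function(peak, sd) {
    lam <- uptake * peak
    v <- if (noise) with_seed(sd, array(stats::rpois(length(lam), lam), d))
    else lam
    image_volume(v, spec$spect_spacing, spec$spect_origin,
                 if (peak == spec$vent_peak) "SPECT-V" else "SPECT-P")
  }
  list(vent = make_study(spec$vent_peak, seed),
       perf = make_study(spec$perf_peak, seed + 1L),
       truth = truth)
}

draw_defects <- function(spec, surfaces, seed, max_frac = 0.30) {
  with_seed(seed, {
    n <- sample(1:3, 1)
    out <- list()
    for (i in seq_len(n)) {
      side <- sample(c("left", "right"), 1)
      g <- surfaces[[side]]$geom
      # peripheral placement: most of the way from the lung center toward
      # the lateral/basal surface
      dir <- c(sign(g$center[1]) * stats::runif(1, 0.5, 1),
               stats::runif(1, -1, 0.3), stats::runif(1, -0.7, 0.7))
      dir <- dir / sqrt(sum(dir^2))
      fr <- stats::runif(1, 0.6, 0.85)
      center <- g$center + fr * dir * c(g$a, g$b, g$c)
      radius <- stats::runif(1, 25, 42)
      mult <- stats::runif(1, 0, 0.25)
      out[[i]] <- list(side = side, center = center, radius_mm = radius,
                       multiplier = mult)
    }
    out
  })
}

#' Generate a reproducible phantom cohort
#'
#' Emulates a training/evaluation split: `n_train` defect-free training
#' cases and `n_eval` evaluation cases of which `n_defect` carry matched
#' peripheral V+P defects (the obstructive-disease phenotype). Returns a
#' manifest tibble plus per-case parameter sets; volumes are rendered
#' lazily with [realize_case()] so a 77-case cohort does not occupy memory.
#'
#' @param n_train,n_eval cohort sizes (defaults 57 and 20).
#' @param spec a `phantom_spec`.
#' @param n_defect evaluation cases carrying defects (default 12).
#' @return a `phantom_cohort`: list with `manifest` (tibble: `case_id`,
#'   `role`, `seed`, `n_defects`, `truth_left_ml`, `truth_right_ml`) and
#'   `cases` (per-case surface/defect parameter sets).
#' @export
make_cohort <- function(n_train = 57, n_eval = 20, spec = phantom_spec(),
                        n_defect = min(12, n_eval)) {
  stopifnot(n_train >= 1, n_eval >= 1)
  n <- n_train + n_eval
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sd_i <- case_seed(spec, i)
    role <- if (i <= n_train) "train" else "eval"
    surfaces <- list(
      left = sample_lung_geometry(spec, "left", seed = sd_i),
      right = sample_lung_geometry(spec, "right", seed = sd_i + 1L)
    )
    defects <- if (role == "eval" && (i - n_train) <= n_defect)
      draw_defects(spec, surfaces, seed = sd_i + 2L) else list()
    truth <- render_truth(surfaces, spec, "ct")
    cases[[i]] <- list(case_id = sprintf("case%03d", i), role = role,
                       seed = sd_i, surfaces = surfaces, defects = defects)
    rows[[i]] <- tibble::tibble(
      case_id = cases[[i]]$case_id, role = role, seed = sd_i,
      n_defects = length(defects),
      defect_radius_mm = if (length(defects))
        paste(round(vapply(defects, `[[`, numeric(1), "radius_mm")),
              collapse = ";") else "",
      truth_left_ml = mask_volume_ml(truth$left),
      truth_right_ml = mask_volume_ml(truth$right)
    )
  }
  structure(list(manifest = dplyr::bind_rows(rows), cases = cases,
                 spec = spec),
            class = "phantom_cohort")
}

#' Render the volumes of one cohort case
#'
#' @param cohort a `phantom_cohort`.
#' @param case_id case identifier or index.
#' @param noise render with noise (default TRUE).
#' @return a `phantom_case`: list with `ct`, `vent`, `perf`, `truth_ct`,
#'   `truth_spect` (each truth a list `left`, `right`), `case_id`, `role`,
#'   `defects`.
#' @export
realize_case <- function(cohort, case_id, noise = TRUE) {
  i <- if (is.numeric(case_id)) case_id
  else match(case_id, cohort$manifest$case_id)
  cs <- cohort$cases[[i]]
  ct <- render_ct(cs$surfaces, cohort$spec, seed = cs$seed + 11L, noise = noise)
  sp <- render_spect(cs$surfaces, cohort$spec, defects = cs$defects,
                     seed = cs$seed + 13L, noise = noise)
  structure(list(case_id = cs$case_id, role = cs$role, defects = cs$defects,
                 ct = ct$ct, truth_ct = ct$truth,
                 vent = sp$vent, perf = sp$perf, truth_spect = sp$truth),
            class = "phantom_case")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d train + %d eval cases (seed %s)\n",
              sum(x$manifest$role == "train"), sum(x$manifest$role == "eval"),
              format(x$spec$seed)))
  invisible(x)
}
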