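#' Build left/right training shapes from a cohort's CT volumes
#'
#' For every training case: render the CT, run the semi-automated CT lung
#' segmentation, extract slice contours, and parameterize both lungs. Cases
#' where any stage fails are skipped with a diagnostic (mirroring how
#' un-parameterizable studies would be excluded from a training set).
#'
#' @param cohort a `phantom_cohort`.
#' @param n_between N, points per arc (default 20).
#' @param hu_threshold CT threshold (default -320 HU).
#' @param noise render CT with noise (default TRUE).
#' @return list with `left`, `right` (lists of `lung_shape`s) and `failed`
#'   (character vector of case ids).
#' @export
extract_training_shapes <- function(cohort, n_between = 20,
                                    hu_threshold = -320, noise = TRUE) {
  ids <- cohort$manifest$case_id[cohort$manifest$role == "train"]
  left <- list(); right <- list(); failed <- character()
  for (id in ids) {
    res <- tryCatch({
      cs <- realize_case(cohort, id, noise = noise)
      seg <- segment_ct_lungs(cs$ct, hu_threshold = hu_threshold)
      list(
        left = contours_to_shape(
          suppressWarnings(extract_slice_contours(seg$left)),
          n_between = n_between, side = "left"),
        right = contours_to_shape(
          suppressWarnings(extract_slice_contours(seg$right)),
          n_between = n_between, side = "right")
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("training case ", id, " skipped: ", conditionMessage(res),
              call. = FALSE)
      failed <- c(failed, id)
    } else {
      left[[id]] <- res$left
      right[[id]] <- res$right
    }
  }
  list(left = left, right = right, failed = failed)
}

#' Run the desk-scale synthetic benchmark
#'
#' The full experiment on a synthetic cohort: simulate `n_train + n_eval`
#' phantom cases, build the CT-derived training shapes, train the two shape
#' models, segment every evaluation study on its V/P sum image, and score
#' the results against the phantom ground truth (overlap on the SPECT grid)
#' and against the semi-automated CT reference (volumes). Every random draw
#' derives from `seed`, so a repeated run is identical.
#'
#' @param seed master seed.
#' @param n_train,n_eval cohort sizes (defaults 57 and 20).
#' @param n_defect evaluation cases with matched peripheral defects
#'   (default 12).
#' @param spec optional `phantom_spec`; default `phantom_spec(seed = seed)`.
#' @param n_between,variance_fraction,n_iter,b_limit model/fit parameters.
#' @return an `asm_benchmark`: list with `per_case` (tibble, one row per
#'   evaluated lung), `summary` (mean +/- SD per side, percent scale),
#'   `volumes` (per-side paired CT-vs-SPECT comparison), `models`,
#'   `manifest`, `failed_train`, `failed_eval`.
#' @export
reproduce_benchmark <- function(seed = 1, n_train = 57, n_eval = 20,
                                n_defect = min(12, n_eval), spec = NULL,
                                n_between = 20, variance_fraction = 0.95,
                                n_iter = 10,
                                b_limit = c("paper", "classic")) {
  b_limit <- match.arg(b_limit)
  if (is.null(spec)) spec <- phantom_spec(seed = seed)
  cohort <- make_cohort(n_train = n_train, n_eval = n_eval, spec = spec,
                        n_defect = n_defect)
  shapes <- extract_training_shapes(cohort, n_between = n_between)
  models <- list(
    left = train_shape_model(unname(shapes$left),
                             variance_fraction = variance_fraction),
    right = train_shape_model(unname(shapes$right),
                              variance_fraction = variance_fraction)
  )
  eval_ids <- cohort$manifest$case_id[cohort$manifest$role == "eval"]
  rows <- list(); failed_eval <- character()
  for (id in eval_ids) {
    res <- tryCatch({
      cs <- realize_case(cohort, id)
      fit <- segment_study(cs$vent, cs$perf, models$left, models$right,
                           n_iter = n_iter, b_limit = b_limit)
      ctseg <- segment_ct_lungs(cs$ct)
      purrr::map_dfr(c("left", "right"), function(side) {
        f <- fit[[side]]
        if (!inherits(f, "asm_fit")) stop(side, " fit failed")
        ov <- overlap(cs$truth_spect[[side]], f$mask)
        ov_ct <- overlap(cs$truth_ct[[side]], ctseg[[side]])
        defs <- Filter(function(d) d$side == side, cs$defects)
        cov <- defect_coverage(cs, f$mask, side)
        tibble::tibble(
          case_id = id, side = side,
          dice = ov$dice, sensitivity = ov$sensitivity,
          precision = ov$precision,
          auto_ml = f$volume_ml,
          ref_ct_ml = mask_volume_ml(ctseg[[side]]),
          ct_dice = ov_ct$dice,
          truth_spect_ml = mask_volume_ml(cs$truth_spect[[side]]),
          n_defects = length(defs),
          defect_coverage = cov,
          final_disp_mm = f$trace$mean_disp_mm[nrow(f$trace)],
          final_disp_voxel = f$trace$mean_disp_mm[nrow(f$trace)] / f$voxel_mm
        )
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("evaluation case ", id, " failed: ", conditionMessage(res),
              call. = FALSE)
      failed_eval <- c(failed_eval, id)
    } else rows[[id]] <- res
  }
  per_case <- dplyr::bind_rows(rows)
  summary <- per_case |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(
      n = dplyr::n(),
      dice_pct = mean(.data$dice) * 100,
      dice_sd_pct = stats::sd(.data$dice) * 100,
      sensitivity_pct = mean(.data$sensitivity) * 100,
      sensitivity_sd_pct = stats::sd(.data$sensitivity) * 100,
      precision_pct = mean(.data$precision) * 100,
      precision_sd_pct = stats::sd(.data$precision) * 100,
      auto_ml_mean = mean(.data$auto_ml),
      auto_ml_sd = stats::sd(.data$auto_ml),
      ref_ct_ml_mean = mean(.data$ref_ct_ml),
      ref_ct_ml_sd = stats::sd(.data$ref_ct_ml),
      .groups = "drop"
    )
  volumes <- per_case |>
    dplyr::group_by(.data$side) |>
    dplyr::group_modify(~ compare_volumes(.x$ref_ct_ml, .x$auto_ml)) |>
    dplyr::ungroup()
  structure(
    list(per_case = per_case, summary = summary, volumes = volumes,
         models = models, manifest = cohort$manifest,
         failed_train = shapes$failed, failed_eval = failed_eval,
         seed = seed),
    class = "asm_benchmark"
  )
}

# fraction of ground-truth voxels inside this side's defect spheres that the
# fitted mask covers (only meaningful for cases with defects)
defect_coverage <- function(case, mask, side) {
  defs <- Filter(function(d) d$side == side, case$defects)
  if (length(defs) == 0L) return(NA_real_)
  truth <- case$truth_spect[[side]]
  pts <- grid_points(dim(truth$voxels), truth$spacing, truth$origin)
  region <- rep(FALSE, nrow(pts))
  for (d in defs)
    region <- region | rowSums(sweep(pts, 2, d$center)^2) < d$radius_mm^2
  region <- array(region, dim(truth$voxels)) & truth$voxels > 0
  if (!any(region)) return(NA_real_)
  sum(mask$voxels[region] > 0) / sum(region)
}

#' @export
print.asm_benchmark <- function(x, ...) {
  cat(sprintf("<asm_benchmark> seed %s: %d lungs evaluated\n", x$seed,
              nrow(x$per_case)))
  print(x$summary)
  invisible(x)
}

#' Per-lung benchmark results
#' @param x an `asm_benchmark`.
#' @param ... unused.
#' @return the per-case tibble.
#' @export
tidy.asm_benchmark <- function(x, ...) x$per_case

#' One-row-per-side benchmark summary
#' @param x an `asm_benchmark`.
#' @param ... unused.
#' @return summary tibble joined with the volume comparison.
#' @export
glance.asm_benchmark <- function(x, ...) {
  dplyr::left_join(x$summary, x$volumes, by = "side")
}
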