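#' Voxel overlap statistics between a reference and a test mask
#'
#' Dice `= 2 TP / (2 TP + FP + FN)` (equivalently `2|X ∩ Y| / (|X| + |Y|)`),
#' sensitivity `= TP / (TP + FN)` and precision `= TP / (TP + FP)`, where X
#' is the reference and Y the automated segmentation. When a denominator is
#' zero (empty reference and/or test), the fraction is reported as 0 and the
#' row is flagged `degenerate`, so batch evaluation never aborts on a failed
#' case.
#'
#' @param reference,test binary `image_volume`s on the same grid.
#' @return one-row tibble with `tp`, `fp`, `fn`, `dice`, `sensitivity`,
#'   `precision`, `degenerate`.
#' @export
overlap <- function(reference, test) {
  stopifnot(inherits(reference, "image_volume"), inherits(test, "image_volume"))
  if (!identical(dim(reference$voxels), dim(test$voxels)))
    stop("reference and test masks are on different grids")
  x <- reference$voxels > 0
  y <- test$voxels > 0
  tp <- sum(x & y)
  fp <- sum(!x & y)
  fn <- sum(x & !y)
  safe <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    dice = safe(2 * tp, 2 * tp + fp + fn),
    sensitivity = safe(tp, tp + fn),
    precision = safe(tp, tp + fp),
    degenerate = (tp + fn) == 0 || (tp + fp) == 0
  )
}

#' Mask volume in milliliters
#'
#' @param mask a binary `image_volume`.
#' @return voxel count times voxel volume, in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "image_volume"))
  if (!is_binary_mask(mask)) stop("mask values must all be 0 or 1")
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Paired volume comparison (Bland-Altman style bias and correlation)
#'
#' Bias is `mean(a - b)`: with `a` the reference (CT) volumes and `b` the
#' SPECT volumes, a negative bias means the SPECT volumes are larger than
#' the reference — the sign convention of the reported volumetric
#' differences. Also returns the SD of the differences and the Pearson
#' correlation with its two-sided p-value; zero variance in either series
#' leaves the correlation `NA` with a flag.
#'
#' @param vols_a,vols_b equal-length numeric vectors of volumes (ml),
#'   `n >= 3`.
#' @return one-row tibble with `n`, `bias_ml`, `sd_ml`, `r`, `p_value`,
#'   `r_defined`.
#' @export
compare_volumes <- function(vols_a, vols_b) {
  if (length(vols_a) != length(vols_b))
    stop("paired volume lists have different lengths")
  n <- length(vols_a)
  if (n < 3) stop("need at least 3 paired volumes")
  d <- vols_a - vols_b
  if (stats::sd(vols_a) == 0 || stats::sd(vols_b) == 0) {
    r <- NA_real_; p <- NA_real_; ok <- FALSE
  } else {
    ct <- stats::cor.test(vols_a, vols_b)
    r <- unname(ct$estimate); p <- ct$p.value; ok <- TRUE
  }
  tibble::tibble(n = n, bias_ml = mean(d), sd_ml = stats::sd(d),
                 r = r, p_value = p, r_defined = ok)
}
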