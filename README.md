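# spectasm

Automatic lung segmentation in ventilation/perfusion (V/P) SPECT images
using 3D active shape models trained on CT-derived lung shapes.

## Why a shape prior

V/P SPECT depicts lung *function*. In obstructive lung disease, peripheral
regions with matched ventilation **and** perfusion loss are indistinguishable
from background, so intensity thresholding truncates the lung exactly where
quantification matters most. `spectasm` constrains the segmentation with a
statistical model of lung *anatomy*: a point-distribution model trained on
CT-derived lung shapes, fitted to the V/P sum image, that can only produce
shapes the training population makes plausible — a matched defect is bridged
by anatomy instead of being carved out by the threshold.

## The model

Each lung is a corresponded point set: per coronal slice, three landmarks at
contour extrema (top, bottom-left, bottom-right) with each arc resampled to
`N − 1` equidistant points, stacked over 30 resampled slices:

    X = (x₁, y₁, z₁, …, xₙ, yₙ, zₙ),   n = 3(N − 1) × 30

Training shapes are centered, scaled to unit Frobenius size
`Vol = (Σᵢ xᵢ² + yᵢ² + zᵢ²)^{1/2}`, aligned by generalized Procrustes
iteration (SVD/Kabsch rotations, iterate until `D = Σᵢ|Xᵢ − X̄|² < 1`),
projected to the tangent space at the mean (scaling by `1/(Xᵢ·X̄)`), and
summarized by PCA with `1/m` covariance normalization, keeping the smallest
number of modes `t` reaching 95% of total variance. A shape instance is

    X = X̄ + P b ,    bᵢ ∈ [−λᵢ√2, λᵢ√2]

Segmentation of a study: sum the max-normalized ventilation and perfusion
volumes; threshold at 15% of the maximum to initialize location, scale and
left/right split; place the mean shape (volume-matched scale, principal-axis
rotation, centroid translation); then iterate 10 times per lung:
move every point along its outward surface normal to the steepest intensity
falloff (with two overrides on the [0,1] scale — intensity > 0.30 moves the
point outward one step, < 0.05 moves it inward one step), then clip the
shape's model coefficients to the plausibility box above. Left and right
lungs use independent models. Validation uses Dice, sensitivity, precision
and Bland–Altman volume bias against a CT reference segmentation.

A digital CT/SPECT phantom (two deformable lung-like bodies with known
ground-truth masks, matched peripheral defects, CT/SPECT noise) provides the
training and evaluation cohorts for the end-to-end benchmark; see the
methods vignette (`vignettes/spectasm-methods.Rmd`) for every modelling and
numerical choice.

## Worked example

Simulate a small cohort, train both lung models on CT-derived contours, and
segment a study carrying a matched peripheral defect:

```r
library(spectasm)

spec    <- phantom_spec(seed = 42)
cohort  <- make_cohort(n_train = 8, n_eval = 2, spec = spec, n_defect = 1)
shapes  <- extract_training_shapes(cohort)
model_left  <- train_shape_model(shapes$left)
model_right <- train_shape_model(shapes$right)
model_right
#> <asm_model> side right: 8 training shapes, 6/8 modes (96.8% variance), 1710 points

tidy(model_right)
#> # A tibble: 6 × 6
#>    mode eigenvalue prop_variance cum_prop_variance b_limit_paper b_limit_classic
#>   <int>      <dbl>         <dbl>             <dbl>         <dbl>           <dbl>
#> 1     1   0.00386         0.413              0.413      0.00546           0.186
#> 2     2   0.00198         0.212              0.624      0.00280           0.134
#> 3     3   0.00160         0.170              0.795      0.00226           0.120
#> 4     4   0.000697        0.0745             0.869      0.000986          0.0792
#> # ℹ 2 more rows

case <- realize_case(cohort, "case009")    # evaluation case with a defect
fit  <- segment_study(case$vent, case$perf, model_left, model_right)
fit
#> <asm_segmentation>
#>   left: 1708 ml after 10 iterations (final mean step 0.56 mm)
#>   right: 2440 ml after 10 iterations (final mean step 0.16 mm)

overlap(case$truth_spect$right, fit$right$mask)
#> # A tibble: 1 × 7
#>      tp    fp    fn  dice sensitivity precision degenerate
#>   <int> <int> <int> <dbl>       <dbl>     <dbl> <lgl>
#> 1  7357   403   141 0.964       0.981     0.948 FALSE
```

The fitted right lung overlaps the phantom's ground truth with Dice 0.964
despite the matched defect; `tidy(fit)` exposes the per-iteration mean point
displacement and the coefficient usage of the plausibility box, and
`autoplot(fit)` overlays the fitted contours on a coronal slice of the sum
image.

Everything is a plain tibble or a small S3 object with `tidy()`, `glance()`
and `autoplot()` methods, so results pipe straight into dplyr/ggplot2.

## Command line

A thin CLI over the same functions lives at `inst/cli/spect-asm.R`
(subcommands `simulate`, `ct-segment`, `train`, `segment`, `evaluate`,
`reproduce`), reading and writing NIfTI/MetaImage volumes, CSV contours and
JSON model archives:

```sh
Rscript inst/cli/spect-asm.R segment --vent v.nii.gz --perf p.nii.gz \
  --model-left left.asm.json --model-right right.asm.json --out-dir results/
```

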