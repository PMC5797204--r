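---
title: "Active shape model lung segmentation for V/P SPECT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active shape model lung segmentation for V/P SPECT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ventilation/perfusion (V/P) SPECT images show lung *function*, not lung
*anatomy*. In obstructive lung disease, peripheral regions may ventilate and
perfuse so poorly that they are indistinguishable from background in both
studies — a *matched defect*. Intensity thresholding then truncates the lung,
and any downstream quantification (functional volumes, gradients, defect
extent) inherits the error. The remedy implemented here is a statistical
shape prior: the segmentation may only produce lung shapes that a training
population of real (CT-derived) lung shapes could plausibly contain, so a
signal void at the periphery is bridged by anatomy rather than followed by
the threshold.

`spectasm` implements the full pipeline: CT reference segmentation, shape
parameterization, point-distribution-model training, ASM fitting on the
ventilation+perfusion sum image, validation metrics, and a digital phantom
that stands in for patient data.

## Shape representation

Each lung is described by corresponded points on coronal slice contours.
Per slice, three landmarks are placed at contour extrema — A at the top, B
at the bottom-left, C at the bottom-right — and each landmark-to-landmark
arc is resampled to $N-1$ points equally spaced by arc length (the landmark
itself is the first point of its arc), giving $3(N-1)$ points per slice.
Stacks are then resampled along straight lines joining corresponding points
to exactly 30 equally spaced slices spanning the shape's own z-range, so
every lung becomes a vector

$$X = (x_1, y_1, z_1, \dots, x_n, y_n, z_n), \qquad n = 3(N-1)\times 30 .$$

`n_between` ($N$) defaults to 20 (57 points per slice, 1710 points per
lung): enough to resolve a 64×64 SPECT grid without oversampling the
training contours. The slice count 30 matches the average number of 5-mm CT
slices covering adult lungs, which minimizes resampling distortion of the
training set.

Two deliberate interpretation choices, flagged because the per-slice count
wording is ambiguous: the count is *inclusive* of landmarks (three arcs of
$N-1$ points each), and "bottom left/right" are operationalized as the
laterally extreme vertices of the contour half below the vertex centroid,
with ties broken to the lowest point index so landmarking is deterministic.

## Training: alignment, tangent space, PCA

Training shapes are centered on their centroids, scaled to unit Frobenius
size $\mathrm{Vol} = (\sum_i x_i^2+y_i^2+z_i^2)^{1/2}$, and rotated into a
common frame by generalized Procrustes iteration: all shapes are first
rotated onto the first shape of the set (a deterministic stand-in for an
arbitrary reference), then repeatedly onto the recomputed mean until the
total squared distance to the mean satisfies $D < 1$ (in unit-size
coordinates) or 50 iterations elapse. The optimal rotation between two
corresponded point sets is the SVD (Kabsch) solution with a determinant
sign-correction that excludes reflections. Although the similarity
transform is often written with two rotation angles, the SVD solution is a
general 3-parameter 3D rotation, and that is what is implemented
throughout.

Aligned unit-size shapes live on a hypersphere; before PCA each is scaled
by $1/(X_i \cdot \bar{X})$, projecting it onto the tangent plane at the
mean and linearizing the shape space. The covariance is normalized by
$1/m$ (not $1/(m-1)$); the eigenvalue scale and the plausibility bounds
below are consistent with that choice. Eigenpairs are computed from the SVD
of the centered $m \times d$ data matrix rather than the explicit
$d \times d$ covariance ($d \approx 5000 \gg m$); a test verifies the
equivalence against `eigen()` on a small problem. The smallest number $t$
of leading modes reaching 95% of total variance is retained; trailing
modes, the ones dominated by outliers and residual misalignment, are
discarded. A shape instance is $\bar{X} + P b$.

## Segmentation

1. **Sum image.** Ventilation and perfusion are each divided by their own
   maximum and summed. For rule evaluation the sum is rescaled once more to
   $[0,1]$ by its own maximum (its raw range is $[0,2]$).
2. **Binary initialization.** Threshold at 15% of the sum image maximum.
   This deliberately overestimates the lungs but yields the centroid,
   z-limits and volume per side. The volume is split into left and right at
   the sagittal plane through the valley of the mask's left–right marginal
   profile; the valley is located between the two dominant local maxima of
   the lightly smoothed profile, which stays correct when a matched defect
   weakens one lung's signal.
3. **Placement.** The model mean is scaled so its enclosed volume (slice
   shoelace areas × slice gap) matches the side's binary volume, rotated so
   its principal axes coincide with the binary mask's principal axes (the
   point-correspondence SVD rule degenerates to this axis match against a
   mask), and translated onto the binary centroid. Principal-axis signs
   follow a fixed convention (largest component positive, third axis
   right-handed), which is deterministic and anatomically stable because
   the lung's axes have clearly distinct extents.
4. **Boundary update.** For every point, the $[0,1]$ sum image is sampled
   by trilinear interpolation along the outward surface normal over ±5
   voxels at half-voxel steps (±34 mm and 3.4 mm at the 6.8-mm SPECT
   spacing; both configurable). The candidate position is the minimum of
   the finite-difference derivative — the steepest falloff. Two overrides
   avoid local minima: intensity at the current point above 0.30 moves the
   point *outward* one step; below 0.05 moves it *inward* one step (this is
   what shrinks a contour that reached outside the lungs). The outward
   normal is the cross product of the in-slice tangent and the
   across-slice tangent (one-sided at the end slices), falling back to the
   in-plane radial direction if degenerate.
5. **Plausibility constraint.** The updated shape is pose-aligned to the
   model mean (centroid, unit Frobenius scale, SVD rotation), projected to
   $b = P^\top(X' - \bar{X})$, and every $b_i$ is clipped to
   $[-\lambda_i\sqrt{2},\ \lambda_i\sqrt{2}]$ before reconstruction and
   mapping back through the inverse pose.
6. Steps 4–5 repeat as one shared loop for a fixed 10 iterations, which is
   sufficient for convergence (the mean per-point step falls well below
   half a voxel on defect-free phantoms); the fitted shape is then
   rasterized per slice (polygon scan fill at the target grid, nearest
   shape slice per grid plane, boundary points counted inside).

### The $\lambda_i\sqrt{2}$ box

The plausibility box is implemented literally on the *eigenvalue*,
$\pm\lambda_i\sqrt{2}$. Dimensional analysis would suggest the standard
deviation $\sqrt{\lambda_i}$ — the classic ASM box is $\pm 3\sqrt{\lambda_i}$
— and because unit-size shape eigenvalues are small
($\lambda_i \ll \sqrt{\lambda_i}$), the literal box is *far tighter*: in
practice the fit keeps essentially the mean shape and lets the similarity
pose (re-estimated every iteration) do most of the work. Both behaviors are
available via `b_limit = "paper"` (default) or `"classic"`; a test documents
that a shape excursion clipped under the default box passes untouched under
the classic one. The tight default is also what makes matched defects
largely harmless to the contour: the shape cannot collapse into the signal
void.

Left and right lungs are fitted by independent models; the whole loop is
deterministic, so identical inputs give bit-identical masks.

## Validation metrics

Dice $2|X\cap Y|/(|X|+|Y|)$, sensitivity $TP/(TP+FN)$ and precision
$TP/(TP+FP)$ are computed per lung against a reference mask on the same
grid; empty-denominator cases report 0 with a `degenerate` flag so batch
runs never abort. Volume comparisons report Bland–Altman style bias ± SD
with Pearson correlation; bias is `mean(reference − test)`, so *negative
values mean the test volumes are larger than the CT reference*.

## The digital phantom

The phantom stands in for a patient cohort (57 training + 20 evaluation
subjects by default, 12 of the evaluation cases carrying matched defects).
Each lung is a tapered superellipsoid (sup–inf exponent 3, apex taper 0.25)
with a dome-shaped diaphragm floor, minus a heart ellipsoid placed left of
the midline and antero-inferiorly — so the concavity bites deeper into the
left lung and the left lung is systematically smaller, as in adult anatomy.
An 8-mm mediastinal septum guarantees the two lungs never touch. Planted
variability modes (global scale, sup–inf stretch, lateral shear, diaphragm
height, concavity depth) are drawn per case from normal distributions
clamped at ±1.5 SD — the same plausibility-box logic used when sampling any
statistical shape model — with SDs chosen so that default-cohort truth
volumes stay in the adult reference range 1000–3500 ml with left ≈ 1700 ml
and right ≈ 2100 ml on average (volume CV just under 20%).

CT rendering uses three levels (−1000 HU air, +40 HU body, −800 HU lung)
plus Gaussian noise (σ = 20 HU) on a 128×128×60 grid at 3×3×5 mm.
SPECT rendering uses a plateau with a 20% apex-to-base linear gradient,
2% background, spherical matched defects (multiplier 0–0.25, radius 25–42
mm, peripheral placement), a Gaussian system-resolution blur of 2 voxels
FWHM, and Poisson counting noise at peak scales of 50 (ventilation) and
150 (perfusion) counts on a 64×64×40 grid at 6.8 mm. Both grids share one
physical frame, i.e. the phantom is emitted already co-registered.

What the phantom does *not* emulate: attenuation and scatter, respiratory
motion, reconstruction artifacts, airway/vessel structure inside the lung,
inter-observer truth variability, and the full anatomical diversity of a
patient population. Passing the synthetic benchmark therefore shows the
algorithm's mechanics are correct under controlled conditions with clean
ground truth; it does not certify clinical performance.

## Numerical choices and degenerate inputs

* CT threshold default −320 HU (configurable); ambient air is removed by
  discarding thresholded components touching the volume border *before*
  picking the two largest components; 3D closing (radius 1) then per-slice
  hole filling removes vessel holes. Fewer than two interior components is
  an explicit "lungs not found" error.
* Contours are traced on the 0.5 iso-level of the zero-padded slice, so
  border-touching masks still close; multi-component slices keep the
  largest with a warning; empty slices are omitted.
* Profile samples outside the image clamp to the border voxel value.
* A non-positive inner product with the mean during tangent projection
  aborts with an alignment-failure error rather than silently flipping.
* Model files are JSON with numeric arrays base64-encoded as little-endian
  float64, so a reloaded model reproduces `generate_shape()` bit-exactly;
  a schema-version field guards against stale files. NIfTI-1 headers store
  spacing/origin as single-precision floats (a property of the format);
  MetaImage headers are written at full double precision.
* All internal geometry is physical mm; grids only reappear at
  rasterization. Physical coordinates are `origin + index * spacing` with
  0-based indices.

## Problem sizes used by the test suite

The end-to-end benchmark in the tests and the acceptance script uses the
full default cohort: 57 training phantoms at CT resolution and 20
evaluation studies at SPECT resolution, 12 with defects, all derived from
one seed. Unit tests of individual operations use reduced grids
(64×64×36 CT, 48×48×30 SPECT) and 5–6 training shapes, which exercise the
same code paths at a fraction of the cost. These sizes are the package's
chosen experiment scale; they reproduce the benchmark in minutes on a
single core.

## Known limitations

* The reference orientation at placement relies on principal axes of the
  binary mask; grossly asymmetric uptake (e.g. one absent lung) would need
  a different initialization.
* The left/right split assumes a sagittal separating plane, which is
  adequate for lungs but would fail for horseshoe-like morphologies.
* Landmarks B and C on the left lung are geometric, not anatomical, and
  can sit close together on rounded basal contours; the correspondence is
  still consistent because it is defined by the same rule everywhere.
* No appearance model is learned; boundary evidence is the fixed
  profile/override rule set, which is tailored to max-normalized V/P sum
  images.
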