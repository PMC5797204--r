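Package: spectasm
Title: Active Shape Model Lung Segmentation for Ventilation/Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of the lungs in ventilation/perfusion (V/P)
    SPECT studies using three-dimensional active shape models trained on
    CT-derived lung shapes. Provides semi-automated CT lung segmentation and
    contour parameterization, generalized Procrustes alignment and PCA
    point-distribution model fitting, iterative model-to-image fitting on the
    normalized ventilation+perfusion sum image with intensity-profile boundary
    updates and shape-plausibility constraints, overlap and volume validation
    metrics, and a digital CT/SPECT lung phantom generator with known ground
    truth for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    grDevices,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
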