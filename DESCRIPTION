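Package: laminardecode
Title: Depth-Resolved Decoding of Laminar fMRI Signals in Human V1
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for laminar (sub-millimetre) fMRI
    decoding analyses of primary visual cortex: population receptive
    field (pRF) grid fitting and Fourier phase retinotopy, r2-thresholded
    region-of-interest definition over the visual field, assignment of
    voxels to six partially overlapping cortical-depth bins, trial-wise
    GLM beta estimation with a two-gamma haemodynamic response function,
    per-depth linear support-vector decoding with leave-one-run-out
    cross-validation and cross-classification, bootstrap and
    false-discovery-rate first-level inference, a depth-parameterised
    linear mixed model for second-level inference, and back-projection
    of classifier weights into visual space via pRF-weighted averaging.
    Includes a seeded synthetic-subject generator emulating a
    five-condition colour imagery/illusion block design plus rotating
    wedge and expanding ring retinotopic mapping runs, so the whole
    pipeline is testable with known ground truth. Also scores binocular
    rivalry imagery-strength pre-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    nlme,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Classification, FunctionalPrediction
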