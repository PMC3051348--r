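Package: ctphantom
Title: Accuracy and Precision of Threshold-Based CT Volumetry on Digital
    Sphere Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates digital sphere-in-gelatin computed tomography (CT)
    phantoms and quantifies how slice thickness, reconstruction field of
    view, and reconstruction kernel limit the accuracy and precision of
    threshold-based tumor volumetry. Provides partial-volume-correct
    voxelization of analytic sphere phantoms, kernel blur and noise
    emulation, thick-slice synthesis by slice averaging (including
    fractional slices and phase-shift search), calibrated global-threshold
    segmentation with filtered 3D connected components, per-sphere volume
    measurement, and accuracy/precision reporting: percent error summaries,
    coefficients of variation, 95% confidence intervals, origin-forced
    accuracy slopes, one-way ANOVA with Bonferroni correction, and
    minimum-measurable-diameter lookup tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
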