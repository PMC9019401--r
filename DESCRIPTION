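Package: sonosim
Title: Ray-Cast B-Mode Ultrasound Simulation over Attenuation Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates brightness-mode (B-mode) ultrasound images by
    marching rays through three-dimensional attenuation volumes. Echo
    formation is driven by the spatial gradient of a per-voxel attenuation
    value: gradient-based reflection, interface transmittance, and a
    depth-accumulated intensity attenuation integral combine into per-beam
    echo profiles that are log-compressed to 8-bit gray levels, with an
    acoustic-shadow floor applied where the accumulated intensity ratio
    falls below a threshold. Includes a synthetic tissue phantom generator
    with NIfTI input/output, an exponential PCR amplification model with
    relative quantification, ELISA standard-series construction and
    calibration, and hand-implemented evaluation statistics (ROC analysis
    with AUC, Hanley-McNeil standard error and Youden cut-off; Welch
    two-sample comparison), together with a bundled per-subject surfactant
    protein dataset used as a worked statistical fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    png,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
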