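Package: lutracer
Title: Voxel-Based Dosimetry and Lesion Kinetics for Lu-177 Radioligand
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-therapy dosimetry for Lu-177 radioligand therapy from
    multi-time-point quantitative SPECT activity maps.  Provides digital
    phantoms with analytic ground truth, mono-exponential time-activity
    modelling and time-integrated activity, voxel absorbed-dose engines
    (local energy deposition and dose-kernel convolution) with
    partial-volume compensation by the VOI-to-anatomical volume ratio,
    MIRD-style organ self-dose, SUV and metabolic tumor volume
    quantification, EORTC/PERCIST/PSA response classification, and
    multi-cycle per-lesion trajectory summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
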