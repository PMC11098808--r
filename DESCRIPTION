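Package: resmini
Title: Lightweight Residual Networks for Brain Age Slice Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates ResMini, a 10-weighted-layer
    residual convolutional network for classifying age groups from 2D axial
    middle slices of brain MRI volumes. Provides the complete pipeline
    around the network: NIfTI slice extraction, offset-and-flip data
    augmentation, stratified train/validation/test splitting, ADAM training
    with per-epoch history, confusion-matrix metrics, and closed-form
    parameter counting for parameter-economy comparisons against larger
    residual baselines. A synthetic brain-phantom generator makes every
    stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
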