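Package: sgtn
Title: Semantic-Guided Transformer Network for Hyperspectral Crop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based classification of hyperspectral imagery with a compact
    CNN-transformer hybrid. Provides loaders for ENVI rasters and MATLAB v5
    containers, per-class stratified train/validation/test splitting, a
    synthetic labeled-scene simulator with controllable spectral
    confusability, a multi-branch convolutional feature extractor with
    factorized 1x3/3x1 kernels, a semantic-guided attention block that
    derives a sigmoid spatial weight map from a positional-encoding-free
    transformer encoder, a two-stage assembly of the two blocks trained with
    Adam on cross-entropy, overall/average accuracy and Cohen's kappa from
    confusion matrices, repeated-experiment summaries, full-scene
    classification maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    caret
Config/testthat/edition: 3
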