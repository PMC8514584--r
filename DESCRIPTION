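Package: admil
Title: Attention-Based Deep Multiple Instance Learning for Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of microscopy specimen images as
    benign or malignant using attention-based deep multiple instance learning.
    Specimen images are tiled into fixed-size patch instances, filtered by a
    per-image Otsu foreground rule, and grouped into per-case bags carrying a
    single weak label. A small convolutional backbone extracts per-instance
    features that are aggregated by a learned softmax attention layer (or by
    mean pooling for the conventional baseline) and classified by a sigmoid
    head. Includes a seeded synthetic-specimen generator with ground-truth
    patch labels, case-stratified cross-validation, a supervised per-image
    baseline with case-level max aggregation, confusion-matrix metrics, and
    attention-map overlays for interpreting which tiles drive a prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
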