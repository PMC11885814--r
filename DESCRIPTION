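Package: mimlr
Title: Multiplex Image Machine Learning for Label-Free Cell Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies visually similar cell populations from microfluidic
    squeeze-channel experiments by fusing bright-field transit images with
    per-cell biomechanical features (deformation index, transition time,
    maximum velocity, and optionally the deformation-index rate). Provides a
    residual convolutional image encoder, a small feature network, and a
    late-fusion classification head trained jointly; classical tabular
    baselines with five-fold cross-validation; Grad-CAM and t-SNE
    interpretability tools; a synthetic transit-image and feature generator
    calibrated to published population statistics; and a simplified
    two-dimensional spring-ring cell simulator for augmenting training data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
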