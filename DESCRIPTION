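Package: ettcascade
Title: Cascaded Convolutional Localization of Endotracheal Tubes on Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@posteo.net", role = c("aut", "cre"))
Description: A serial three-stage convolutional pipeline for frontal chest
    radiographs: coarse regression of the carina landmark, hard-attention
    cropping around the predicted carina to classify endotracheal tube (ETT)
    presence, and refined regression of the carina and distal ETT tip to
    report the tip-carina distance in centimeters. Ships a compact
    Rcpp/Armadillo convolutional network engine (3x3 conv + batch norm +
    LeakyReLU blocks, stride-2 subsampling, Adam), invertible coordinate-frame
    plumbing between the original, padded, model and crop grids, a
    patient-grouped five-fold cross-validation harness, regex-based radiology
    report parsing, evaluation metrics with confidence intervals, and a
    synthetic radiograph generator with exact ground-truth landmarks so every
    stage is trainable and testable without credentialed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
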