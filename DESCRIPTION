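Package: shadowfold
Title: Family-Fold Cross-Validation Benchmarking for Learned RNA Secondary
    Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify whether learned RNA secondary structure
    predictors generalize across RNA families. Implements a demonstrative
    convolutional network that predicts per-nucleotide pairing probabilities
    (structure "shadows"), converts them into SHAPE-like pseudo-free-energy
    terms for minimum-free-energy folding, and benchmarks the resulting
    pipeline under both k-fold and leave-one-family-out (family-fold)
    cross-validation. Includes connectivity-table and dot-bracket I/O, a
    dynamic-programming reference folding engine with per-nucleotide
    pseudo-energy support, slippage-tolerant base-pair scoring with ROC
    analysis, uniform pseudo-energy "nudge" sweeps, slope/intercept grid
    search, an ordered tree-edit-distance homology audit between training and
    testing splits, and a generator of synthetic RNA families with conserved
    consensus structures for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
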