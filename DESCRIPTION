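Package: efo
Title: Enrichment Factor Optimization for Ranking-Based Linear Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Learns sparse linear scoring models on numeric descriptor tables
    with a binary label by maximizing a ranking-quality function, the product
    of the cluster-profile asymmetry index (Pearson's moment coefficient of
    skewness) and the positive rate of the first cluster. Descriptors are
    pre-filtered by their single-variable top-5% enrichment factor,
    coefficients are optimized by Hooke-Jeeves pattern search with random
    restarts, classification thresholds are derived from the training ranking,
    and score-based probabilities are read off percentile bins of the training
    ranking. Designed for strongly unbalanced binary problems such as
    reactive-metabolite substrate prediction, with a repeated hold-out
    validation harness, calibration sweeps, and a synthetic-data generator
    emulating descriptor tables of that shape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
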