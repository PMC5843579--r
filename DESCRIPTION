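Package: knnqspr
Title: Weighted k-Nearest-Neighbour QSPR Models with Genetic-Algorithm
    Descriptor Selection and Applicability-Domain Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-property relationship (QSPR)
    models from precomputed molecular-descriptor tables using a
    distance-weighted k-nearest-neighbour learner. Provides the full
    modelling workflow: duplicate merging and outlier removal during
    dataset curation, stratified train/test splitting, descriptor
    filtering (missing values, near-constant columns, pairwise
    correlation), autoscaling with saved parameters, genetic-algorithm
    descriptor selection with two-round frequency ranking and forward
    selection, external-validation statistics (RMSE, R2, RMSEP, Q2,
    balanced accuracy), and a two-tier applicability-domain assessment
    combining global leverage with a local five-nearest-neighbour
    similarity index and a per-query confidence level. Includes a
    deterministic synthetic-data generator for testing and a batch
    command-line interface producing tab- or comma-delimited prediction
    reports with nearest-neighbour evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    tidyselect,
    readr,
    ggplot2,
    jsonlite,
    generics,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    withr
Config/testthat/edition: 3
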