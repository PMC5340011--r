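Package: isisen
Title: Iterative Sure Independence Screening with Elastic-Net Penalized
    Binomial Models for Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variable selection for ultra-high-dimensional DNA methylation
    studies of an ordinal metabolic-syndrome index. Fits an elastic-net
    penalized binomial-trials generalized linear model by iteratively
    reweighted least squares with coordinate descent, wraps it in
    (iterative) sure independence screening so that selection happens in a
    screened submodel of manageable size, and stabilizes the selected set
    with Bolasso-style bootstrap frequency thresholds. Includes Beta/M-value
    transforms, K-nearest-neighbour probe imputation, derivation of the
    0-5 metabolic-syndrome index from phenotype records, Hand-Till
    multiclass AUC with cross-validated evaluation, and a synthetic
    generator for correlated (co-methylation-like) designs with planted
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
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
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
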