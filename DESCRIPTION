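Package: pseudotempo
Title: Pseudotemporal Time-Course Analysis of Single-Cell RNA-Seq via
    Pseudo-Bulk Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates annotated single cells into sample-by-cluster
    pseudo-bulk expression profiles carrying mean pseudotime, builds a
    QR-reparametrized natural-cubic-spline design blocked on sample of
    origin, and tests each gene's association with pseudotime under a
    negative-binomial quasi-likelihood model with empirical-Bayes
    dispersion shrinkage. Includes TMM normalization, expression
    filtering, MDS diagnostics, fitted trend curves and heatmap
    matrices, directional hypergeometric over-representation analysis
    against GMT gene-set collections, a synthetic-data generator for
    multi-sample trajectories, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    edgeR,
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
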