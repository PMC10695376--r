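Package: scdeband
Title: Depth-Matched Differential Expression and Per-Cell Gene-Set
    Enrichment for Single-Cell UMI Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for multi-library single-cell RNA-seq UMI count
    matrices: pseudo-bulk median-of-ratios library size factors computed on a
    75%-expressed gene panel, depth equalization by seeded binomial UMI
    downsampling, a differential-expression caller based on the 99% prediction
    band of a linear regression of log2 fold change on the fraction of
    expressing cells (with zero-stripped Mann-Whitney statistics and a 30%
    expressing-cell gate), per-cell preranked gene-set enrichment with
    gene-set randomization nulls, gene-set module scores, cluster composition
    tables, and arcsinh-based hashtag-oligo demultiplexing. Includes a
    negative-binomial synthetic-data generator with planted ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fgsea,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
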