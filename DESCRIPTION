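Package: rnamotifs
Title: Structural Motif and Abstract Shape Analysis of RNA Secondary Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing ensembles of RNA secondary structures through
    coarse-grained abstract shapes and structural motif counts. Parses
    dot-bracket structures into loop-decomposition trees, counts the five
    classical motifs (bonds, helices, hairpin loops, bulges, junctions),
    abstracts structures to RNAshapes-style shape strings (level 5 fully
    supported), folds sequences with a ViennaRNA adapter or a built-in
    Nussinov baseline, estimates shape frequency spectra and their
    cross-ensemble correlation, fits per-motif linear length trends with
    bootstrap confidence intervals, and classifies natural-like versus random
    ensembles from motif counts with cross-validated kNN and PLS-DA. Includes
    a seeded synthetic-data generator producing labelled pseudo-natural versus
    random datasets so the whole pipeline is testable without a database
    download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    class,
    mixOmics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
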