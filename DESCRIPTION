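Package: xgram
Title: Transcriptogram Profiling of Genome-Wide Expression on Seriation-Ordered Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders a gene list by simulated annealing of a network-distance
    cost over a protein-protein association graph, so that functionally
    associated genes become list neighbors, then computes windowed (box-car)
    expression profiles ("transcriptograms") along the ordering.  Provides
    ordering-quality diagnostics (occupation fraction, window modularity),
    per-position differential-expression testing (Welch t, Bonferroni,
    Benjamini-Hochberg and Storey q-values), contrast-to-noise and
    signal-to-noise summaries, Lin's concordance correlation for
    between-laboratory reproducibility, gene-set projection profiles, a
    variance-component decomposition of the replicate design, and a synthetic
    planted-module generator that makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
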