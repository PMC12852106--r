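Package: grnctrl
Title: Structural Controllability Analysis of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structural controllability of directed
    gene regulatory networks inferred from single-cell transcriptomics.
    Computes minimum driver-node sets via maximum bipartite matching,
    classifies edges as critical, redundant or ordinary, summarises network
    topology (density, degree heterogeneity, scale-free degree exponent from
    a log-log CCDF regression), simulates robustness to random edge failure,
    categorises transcription factors by criticality, out-degree and
    expression, and provides the cohort-level statistics (Kruskal-Wallis,
    Dunn's post hoc, Pearson and first-order partial correlation) used to
    compare networks across developmental phases. Includes seeded generators
    for scale-free directed networks and expression tables so the full
    pipeline can be exercised on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
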