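Package: lsanet
Title: Local Similarity Association Networks for Multi-Lake Plankton Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seasonal microbial plankton time series
    sampled in parallel across several nearby shallow lakes. Implements
    rarefaction-based OTU table handling, core-microbiome partitioning
    across lake subsets, Bray-Curtis turnover and time distance decay
    statistics with permutational tests (PERMANOVA, Mantel), a
    from-scratch local similarity analysis engine with bounded time
    delays and permutation significance, signed synchronous and
    time-shifted association networks, weighted topological importance
    (WI^n) keystone identification, and season-preference
    classification. A synthetic multi-lake community generator with
    known ground truth (planted core structure, planted synchronous and
    lagged associations, desiccation events) makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
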