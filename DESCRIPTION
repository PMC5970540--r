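Package: polyrecon
Title: Reconciling Consensus Clustering Solutions into Subtype Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers molecular subtypes in a genes-by-samples expression
    matrix by running subsampled consensus clustering with three base
    algorithms (hierarchical, k-means, non-negative matrix factorization)
    over a sweep of cluster numbers, then reconciles the per-algorithm
    cluster solutions into "subtype communities". Reconciliation builds two
    weighted cluster-overlap networks - one from FDR-adjusted hypergeometric
    overlap tests, one from the proportion of maximum intersection (PMI) -
    and applies weighted label propagation community detection to each; the
    reconciliation with the higher average silhouette width is selected.
    Downstream helpers build (optionally shrunken) per-community centroids
    for Pearson-correlation classification of validation cohorts, compare
    community survival with Kaplan-Meier curves and the log-rank test, and
    generate planted-structure synthetic cohorts for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    igraph,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
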