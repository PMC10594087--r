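Package: pairnet
Title: Longitudinal Symptom-Network Analysis for Paired Ordinal Panels
Version: 0.1.0
Authors@R: person("pairnet", "developers", role = c("aut", "cre"),
    email = "pairnet@example.org")
Description: Estimation and comparison of regularized partial-correlation
    networks from paired (baseline / follow-up) panels of ordinal scale
    items, such as clinical symptom ratings scored 0-6.  Provides a
    nonparanormal (rank-based Gaussianizing) transformation, an
    EBIC-selected graphical LASSO estimator of the partial-correlation
    network, node centrality indices (strength, closeness, betweenness)
    and global strength, nonparametric and case-dropping bootstraps for
    edge accuracy and centrality stability, a dependent-samples
    permutation network-comparison test with Holm-corrected edge-level
    tests, signed-network spinglass community detection with
    partition-frequency tallying, and a latent-Gaussian synthetic-data
    generator with planted block network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
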