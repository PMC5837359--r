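Package: tauconnect
Title: Tau Burden and Functional Connectome Graph Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Links regional tau-PET binding potential to resting-state
    functional-connectome graph properties across disease groups. Builds
    Fisher-z association matrices from node time series, thresholds them at
    proportional densities over a maximum-spanning-tree backbone, computes
    nodal graph metrics with degree-preserving null-model normalization, and
    runs the tau-network statistical pipeline: node-wise metric-tau
    correlations, subject tau-burden regressions, moderation (interaction)
    analysis, node-wise gradient maps with sign tests, and the Jennrich test
    for equality of correlation matrices. A synthetic-cohort generator with
    planted, recoverable effect sizes stands in for undeposited neuroimaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
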