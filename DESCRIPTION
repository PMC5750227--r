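Package: netspread
Title: Network-Spread Modeling of Cortical Thinning in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing the network-propagation hypothesis of
    neurodegeneration with longitudinal cortical thickness data. Computes a
    connectivity-weighted "disease exposure" statistic from a subcortical
    atrophy reservoir, relates it to vertex-wise cortical thinning with
    Spearman correlation, permutation tests and bootstrap confidence
    intervals, and compares functional, structural and Euclidean-distance
    propagation models. Includes a longitudinal group-by-time contrast with
    permutation cluster correction, intrinsic-network summaries, clinical and
    cerebrospinal-fluid statistics, and a synthetic-data generator that
    emulates the statistical structure of a two-group two-timepoint
    cortical-thickness study so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
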