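Package: sdnet
Title: System Difference and Related Complexity Measures for Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes System Difference (SD), a degree-distribution metric that
    quantifies the average non-overlap between the input and output neighbour
    sets of node pairs in a directed graph, together with Average Connectedness
    (the mean of the transitive reachability matrix) and two integrated-
    information measures for stationary linear Gaussian dynamics on the same
    connection matrices: the 2003 effective-information Phi (minimum
    information bipartition, full subset search) and the lag-tau empirical Phi.
    Includes the random weakly-connected digraph generators (Bernoulli,
    fixed-column normalized, uniform-over-density) with isomorph rejection
    used to study how SD relates to density, cliques, path length, motif
    censuses and Phi, plus an experiment harness that reproduces those
    comparisons on freshly generated populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
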