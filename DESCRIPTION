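Package: BrainNetEvo
Title: Functional Brain Network Topology and Betweenness-Guided Network Evolution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds thresholded binary functional brain networks from
    region-wise time series, computes graph-topology profiles (global
    efficiency, average clustering, transitivity, edge and long-distance
    edge counts, node betweenness), and evolves healthy-group networks
    toward an Alzheimer-like state by stochastic rewiring in which
    connection and disconnection propensities are controlled by summed
    node betweenness and squared inter-node distance. Evolved networks
    are scored against the two groups with a per-feature linear support
    vector machine. A seeded synthetic-cohort generator with planted
    modular network structure makes the whole pipeline testable without
    any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Rcpp, e1071
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
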