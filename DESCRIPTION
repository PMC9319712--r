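Package: sdhe
Title: Joint Community and Structural-Hole-Spanner Detection in Hyperbolic Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Embeds undirected scale-free networks onto the extended Poincare
    disk and exploits the resulting angular node distribution to detect
    communities and structural hole spanners (bridge nodes between
    communities) in one pass. Provides the nPSO generator for synthetic
    scale-free benchmark networks with planted Gaussian-mixture angular
    communities, a degree-based hyperbolic embedder driven by common-neighbour
    likelihoods, critical-gap community detection by modularity maximisation
    over angular gaps, closed-form critical gaps for uniform and
    Gaussian-mixture angular layouts, an angular-region filter plus two-step
    connectivity ranking for spanner candidates, and tie-strength/CS-score
    evaluation metrics with PageRank, betweenness and two-step baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
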