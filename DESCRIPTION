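Package: readnet
Title: Whole-Brain Functional Network Analysis for Task fMRI Group Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and compares whole-brain functional connectivity networks
    from block-design ROI BOLD time series. Provides a synthetic two-group,
    two-session cohort generator with modular (community-structured)
    correlation patterns; ROI-level general linear models with a canonical
    double-gamma haemodynamic response and discrete-cosine high-pass
    filtering; Pearson/Fisher-z connectivity matrices; sparsity-thresholded
    binary undirected graphs; small-world and efficiency metrics (clustering
    coefficient, characteristic path length, gamma, lambda, sigma, global and
    local efficiency) normalised by degree-preserving rewired null models;
    nodal degree and betweenness centrality; and pooled-variance two-sample
    t statistics with Bonferroni correction across sparsity levels and nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
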