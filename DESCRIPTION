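Package: termitesim
Title: Individual-Based Simulation of Termite Food Transport in Loop Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, individual-based simulation of termite food
    transport through a straight main tunnel carrying a two-segment loop
    tunnel.  Simulated termites shuttle food particles between a food site
    and the nest, choose branches at four nodes with configurable
    probabilities, exchange food by trophallaxis, and form transient traffic
    jams.  The package computes a scaled transport-efficiency statistic,
    runs factorial and Latin-hypercube parameter sweeps with replicate
    averaging, and provides the accompanying analysis stack: one-dimensional
    k-means grouping of efficiency values, branch-probability histograms,
    high/medium/low path coding, a t-SNE embedding, and partial rank
    correlation coefficients (PRCC) for global sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    igraph,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
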