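Package: pathlink
Title: Link Prediction in Bipartite Networks from Path-Induced Local Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts missing links in bipartite networks (drug-target,
    membership, affiliation data) from the local structure around a candidate
    node pair. Connecting simple paths between the pair are enumerated by
    depth-first search, the path-induced subgraph is extracted with the target
    edge removed, nodes are labelled by partition type and hop distance to the
    targets, and the labelled subgraph is scored by a small graph convolutional
    network with mean readout and a sigmoid link scorer trained under mean
    squared error. Includes edge-list readers for KONECT-style files, train/test
    splitting with negative sampling, depth and sparsity experiment harnesses,
    a planted-block synthetic network generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    withr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
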