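Package: muxembed
Title: Multiplex and Multiplex-Heterogeneous Network Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Node embedding for multiplex networks (several layers sharing one
    node set) and multiplex-heterogeneous networks (two multiplexes of
    different node types joined by bipartite edges). Node-to-node similarity
    is computed with Random Walk with Restart on a supra-transition matrix
    (RWR-M / RWR-MH) and embeddings are learned with a VERSE-style
    noise-contrastive estimation objective. Includes edge-feature operators,
    classical link-prediction heuristics, evaluation protocols (connected
    edge splitting via Broder's random spanning tree, link prediction with a
    logistic regressor, network reconstruction precision@K with a random
    forest, bipartite link prediction), and seeded stochastic-block-model
    generators for multiplex and multiplex-heterogeneous fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    glmnet,
    ranger,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
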