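Package: crowdnet
Title: Crowd-Sourced Aggregation and Evaluation of Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gold-standard-free machinery for evaluating and aggregating
    crowd-submitted directed signaling networks. Provides network edge-list
    input/output with layer annotations, similarity scoring of binary edge
    predictions (Jaccard z-score, Matthews correlation coefficient, TPR-FPR)
    with rank aggregation, a beta-binomial mixture model over per-edge vote
    counts fitted by maximum likelihood with an optimal posterior vote
    threshold for consensus-network construction, consensus-score analyses by
    network layer and node, Boolean-logic pruning of a reference network
    against discretized perturbation data via an exact integer program, and
    seeded synthetic generators for layered networks, predictor crowds and
    perturbation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
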