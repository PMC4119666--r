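Package: lpaperc
Title: Community Detection by Label Propagation with Percolation-Transition Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Asynchronous label propagation for community detection in
    undirected weighted or unweighted networks, extended with a prediction of
    the percolation transition: when a vertex faces several maximal labels, it
    adopts the one yielding the smallest resulting community, which delays the
    emergence of the trivial single-community ("monster") solution. Includes a
    purity/degree-gated incomplete-update rule to cut computation, a dual
    network-construction view whose connected components mirror label classes,
    seeded generators for planted-partition (Girvan-Newman style), Erdos-Renyi
    giant-component and complete-graph benchmarks with random edge weightings,
    partition quality metrics (modularity, fraction of vertices classified
    correctly), and a reproducible benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
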