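Package: NetCompare
Title: Comparative Analysis of Multiple Biological Association Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Engine for side-by-side comparison of up to eight biological
    association networks (gene, protein, taxon co-occurrence) supplied as
    delimited edge lists. Computes exact Venn/UpSet intersection regions
    with member retrieval, intersection/exclusive/union comparison graphs
    with per-network membership annotation, global and per-node graph
    properties traced across networks, edge-Jaccard similarity with
    hierarchical clustering of the networks themselves, all-shortest-path
    matrices with preferred intermediate nodes, greedy-modularity community
    detection with pairwise community-transition scoring, and k-filtered
    maximal-clique enumeration with cross-network member tracking. A
    synthetic-network generator (uniform G(n,m), planted partitions,
    overlapping network families) supports benchmarking and testing.
    Results are emitted as machine-readable TSV/JSON/newick.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
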