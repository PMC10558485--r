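Package: hypercores
Title: Hyper-Core Decomposition, Hypercoreness Centrality and
    Higher-Order Dynamics on Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to decompose a hypergraph into (k,m)-hyper-cores,
    nested maximal subhypergraphs in which every node belongs to at
    least k hyperedges of size at least m, and to summarise node
    positions in this double hierarchy through the hypercoreness
    family of centralities. Includes a hyperedge-swap null model that
    preserves hyperedge-size counts and per-node degree vectors, with
    z-score profiles of hyper-core sizes; discrete-time higher-order
    nonlinear SIS/SIR contagion simulators with per-core localization
    summaries; a higher-order naming game with committed minorities
    and seeding strategies; ranking-comparison utilities (top-fraction
    Jaccard overlap, top-fraction averages, correlations); readers for
    hyperedge lists, bipartite edge lists and timestamped contact
    streams; and generators of random and planted-core hypergraphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
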