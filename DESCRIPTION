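Package: netloci
Title: Topological Location of Disease Genes in Biomolecular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes four node-level topological parameters (degree, average
    shortest path length, local clustering coefficient, and betweenness
    centrality) for designated gene sets in an undirected interactome, and
    compares them against random-gene-set and first-order-neighbor null
    models with Mann-Whitney U significance and tie-corrected Spearman rank
    correlations between parameters.  Includes a seeded scale-free
    interactome generator with a planted connector gene set so that the full
    pipeline can be exercised and validated without any external network
    download, plus a command-line driver for end-to-end runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
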