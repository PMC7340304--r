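Package: heatnet
Title: Heatmap Centrality and Super-Spreader Identification in Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies super-spreader nodes in simple undirected networks
    with the heatmap centrality, a shortest-path based measure that scores a
    node by its farness minus the mean farness of its neighbours (more
    negative means more influential). Includes the four classical reference
    centralities (degree, eigenvector, closeness, betweenness via Brandes'
    algorithm), tie-aware node ranking with Spearman and Kendall rank
    correlations, a modified susceptible-infected spreading simulator for
    scoring seed sets, a Barabasi-Albert scale-free network generator with
    ensemble structural summaries and log-log power-law degree fits, plain
    edge-list and GraphML input/output, and a command-line interface for the
    standard experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
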