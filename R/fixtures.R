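#' The 15-node toy network
#'
#' A small connected network of 15 nodes and 19 edges whose two halves are
#' joined by the bridge path through nodes 6 and 8. It is the standard
#' worked example for comparing the five centrality measures: node 3 is the
#' highest-degree hub, but node 6 — whose farness is well below the average
#' of its neighbours' — is the top-ranked super-spreader under the
#' closeness, betweenness and heatmap measures, and the heatmap measure
#' ranks node 10 (the hub of the right half) second rather than the
#' bridge-adjacent node 8.
#'
#' The same edge list ships as a plain-text fixture at
#' `system.file("extdata", "toy15.edgelist", package = "heatnet")`.
#'
#' @return a `netgraph` with 15 nodes and 19 edges.
#' @examples
#' g <- toy_network()
#' summary(g)
#' @export
toy_network <- function() {
  edges <- matrix(c(
    1, 3,  2, 3,  3, 4,  3, 5,  3, 6,  3, 7,  4, 5,  5, 6,  6, 7,  6, 8,
    6, 14, 8, 9,  8, 10, 9, 10, 9, 12, 10, 11, 10, 12, 10, 13, 12, 15
  ), ncol = 2L, byrow = TRUE)
  graph_from_edges(edges)
}

#' Look up a bundled fixture network by name
#'
#' @param name fixture name; currently only `"toy15"`.
#' @return a `netgraph`.
#' @export
fixture_network <- function(name) {
  switch(name,
         toy15 = toy_network(),
         stop(sprintf("unknown fixture '%s' (available: toy15)", name)))
}
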