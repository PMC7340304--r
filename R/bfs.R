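# Internal BFS over the integer adjacency list: hop counts from source s,
# NA for unreachable nodes. Frontier expansion is vectorised so all-pairs
# sweeps stay fast at N ~ a few thousand.
bfs_idx <- function(adj, s, n) {
  dist <- rep.int(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[is.na(dist[nb])]
    d <- d + 1L
    dist[nb] <- d
    frontier <- nb
  }
  dist
}

#' Breadth-first shortest-path distances from one node
#'
#' Hop counts from `source` to every node; unreachable nodes get `Inf`.
#'
#' @param g a `netgraph`.
#' @param source a node label present in `g`.
#' @return an object of class `distance_map`: a named numeric vector of
#'   distances with attributes `source` and `reached` (number of reachable
#'   nodes, including the source).
#' @export
bfs_distances <- function(g, source) {
  stopifnot(inherits(g, "netgraph"))
  s <- node_index(g, source)
  d <- bfs_idx(g$adj, s, g$N)
  out <- as.numeric(d)
  out[is.na(d)] <- Inf
  names(out) <- g$labels
  structure(out, source = g$labels[s], reached = sum(!is.na(d)),
            class = c("distance_map", "numeric"))
}

# all-pairs farness on a connected graph (one BFS per node)
all_farness <- function(g) {
  vapply(seq_len(g$N), function(s) {
    d <- bfs_idx(g$adj, s, g$N)
    if (anyNA(d)) {
      stop("farness undefined on a disconnected graph; take largest_component() first")
    }
    sum(d)
  }, numeric(1L))
}

#' Farness of a node
#'
#' The sum of shortest-path hop counts from `v` to every other node. Defined
#' only on connected graphs (otherwise some distances are infinite).
#'
#' @param g a connected `netgraph`.
#' @param v a node label; if omitted, farness of every node is returned.
#' @return a named numeric vector of farness values.
#' @export
farness <- function(g, v = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (is.null(v)) {
    out <- all_farness(g)
    names(out) <- g$labels
    return(out)
  }
  i <- node_index(g, v)
  d <- bfs_idx(g$adj, i, g$N)
  if (anyNA(d)) {
    stop("farness undefined on a disconnected graph; take largest_component() first")
  }
  stats::setNames(sum(d), g$labels[i])
}

#' Connectivity
#'
#' `is_connected()` tests whether every pair of nodes is joined by a path.
#' `largest_component()` returns the induced subgraph on the largest
#' connected component; ties between equally large components are broken in
#' favour of the one containing the smallest node label.
#'
#' @param g a `netgraph`.
#' @return a logical flag, or a `netgraph`.
#' @export
is_connected <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  !anyNA(bfs_idx(g$adj, 1L, g$N))
}

# component id per node, in discovery order from ascending labels
component_ids <- function(g) {
  comp <- rep.int(NA_integer_, g$N)
  cid <- 0L
  for (s in seq_len(g$N)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    comp[!is.na(bfs_idx(g$adj, s, g$N))] <- cid
  }
  comp
}

#' @rdname is_connected
#' @export
largest_component <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  comp <- component_ids(g)
  sizes <- tabulate(comp)
  keep <- which(comp == which.max(sizes))  # first max = smallest-label tie-break
  induced_subgraph(g, keep)
}

# internal: subgraph on a set of node indices, relabelled compactly
induced_subgraph <- function(g, idx) {
  idx <- sort(idx)
  map <- rep.int(NA_integer_, g$N)
  map[idx] <- seq_along(idx)
  adj <- lapply(g$adj[idx], function(nb) sort(map[nb[!is.na(map[nb])]]))
  m <- sum(vapply(adj, length, integer(1L))) %/% 2L
  structure(list(labels = g$labels[idx], adj = adj,
                 N = length(idx), M = m),
            class = "netgraph")
}

#' Diameter of a connected graph
#'
#' The largest shortest-path distance over all node pairs, by all-pairs BFS.
#'
#' @param g a connected `netgraph`.
#' @return an integer hop count (0 for a single-node graph).
#' @export
graph_diameter <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  dia <- 0L
  for (s in seq_len(g$N)) {
    d <- bfs_idx(g$adj, s, g$N)
    if (anyNA(d)) stop("diameter undefined on a disconnected graph")
    dia <- max(dia, max(d))
  }
  as.integer(dia)
}

#' Clean a raw network into a simple connected graph
#'
#' Applies the standard cleaning pipeline for raw (possibly directed,
#' possibly multi-) edge records: treat edges as undirected, drop loops and
#' duplicate edges, then keep only the largest connected component. The
#' counts of removed nodes and edge records are reported.
#'
#' @param edges a two-column matrix or data frame of raw edge records
#'   (possibly directed, with repeats and loops).
#' @param nodes optional vector of node labels, to declare nodes (e.g.
#'   isolated ones) that appear in no edge record.
#' @return an object of class `preprocess_report`: a list with `graph` (the
#'   cleaned `netgraph`), `nodes_removed`, `edges_removed` and
#'   `made_undirected`.
#' @export
preprocess_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0L && is.null(nodes)) stop("empty input: no edges and no nodes")
  n_records <- nrow(edges)
  raw_nodes <- unique(c(trimws(as.character(edges[, 1L])),
                        trimws(as.character(edges[, 2L])),
                        trimws(as.character(nodes))))
  raw_nodes <- raw_nodes[nzchar(raw_nodes)]
  if (length(raw_nodes) == 0L) stop("empty input: no nodes")
  g0 <- graph_from_edges_allowing_isolates(edges, raw_nodes)
  g <- largest_component(g0)
  structure(list(
    graph = g,
    nodes_removed = length(raw_nodes) - g$N,
    edges_removed = n_records - g$M,
    made_undirected = TRUE
  ), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    "preprocess: %d nodes, %d edges kept; removed %d node(s), %d edge record(s)\n",
    x$graph$N, x$graph$M, x$nodes_removed, x$edges_removed))
  invisible(x)
}

# like graph_from_edges(simplify = TRUE) but keeps declared isolated nodes
graph_from_edges_allowing_isolates <- function(edges, node_labels) {
  labels <- sort_labels(node_labels)
  n <- length(labels)
  if (nrow(edges) == 0L) {
    return(structure(list(labels = labels,
                          adj = rep(list(integer(0)), n),
                          N = n, M = 0L),
                     class = "netgraph"))
  }
  i <- match(trimws(as.character(edges[, 1L])), labels)
  j <- match(trimws(as.character(edges[, 2L])), labels)
  keep <- i != j
  lo <- pmin(i, j)[keep]
  hi <- pmax(i, j)[keep]
  dup <- duplicated(paste(lo, hi))
  lo <- lo[!dup]
  hi <- hi[!dup]
  structure(list(labels = labels, adj = build_adj(n, lo, hi),
                 N = n, M = length(lo)),
            class = "netgraph")
}
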