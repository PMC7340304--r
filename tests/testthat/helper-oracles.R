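# Shared fixtures and independent oracles for the test suite.

# random connected simple graph: random spanning tree + extra random edges
random_connected_graph <- function(n, extra = n) {
  stopifnot(n >= 2L)
  tree <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1L)))
  edges <- tree
  if (extra > 0L && n >= 3L) {
    pairs <- t(utils::combn(n, 2L))
    pick <- sample.int(nrow(pairs), min(extra, nrow(pairs)))
    edges <- rbind(edges, pairs[pick, , drop = FALSE])
  }
  graph_from_edges(edges, simplify = TRUE)
}

path_graph <- function(n) graph_from_edges(cbind(seq_len(n - 1L), 2:n))

complete_graph <- function(n) graph_from_edges(t(utils::combn(n, 2L)))

cycle_graph <- function(n) graph_from_edges(cbind(seq_len(n), c(2:n, 1L)))

star_graph <- function(leaves) graph_from_edges(cbind(1L, 1L + seq_len(leaves)))

# convert a netgraph to an igraph object on the same labels
to_igraph <- function(g) {
  em <- edge_matrix(g)
  ig <- igraph::graph_from_edgelist(cbind(match(em[, 1L], g$labels),
                                          match(em[, 2L], g$labels)),
                                    directed = FALSE)
  ig
}

# brute-force shortest-path oracle: enumerate every simple path between a
# pair, take the minimum length. Exponential; only for tiny graphs.
brute_all_simple_paths <- function(g, from, to) {
  adj <- g$adj
  out <- list()
  recurse <- function(u, visited) {
    if (u == to) {
      out[[length(out) + 1L]] <<- visited
      return(invisible())
    }
    for (w in adj[[u]]) {
      if (!(w %in% visited)) recurse(w, c(visited, w))
    }
  }
  recurse(from, from)
  out
}

brute_distance <- function(g, from, to) {
  if (from == to) return(0L)
  paths <- brute_all_simple_paths(g, from, to)
  if (length(paths) == 0L) return(Inf)
  min(lengths(paths)) - 1L
}

# brute-force betweenness: explicit enumeration of all shortest paths for
# every unordered pair, fractional credit to interior nodes.
brute_betweenness <- function(g) {
  n <- g$N
  cb <- numeric(n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      paths <- brute_all_simple_paths(g, j, k)
      if (length(paths) == 0L) next
      len <- lengths(paths)
      sp <- paths[len == min(len)]
      interior <- table(factor(unlist(lapply(sp, function(p) p[-c(1L, length(p))])),
                               levels = seq_len(n)))
      cb <- cb + as.numeric(interior) / length(sp)
    }
  }
  stats::setNames(cb, g$labels)
}

# reference centrality columns for the toy network, nodes 1..15 (values at
# the precision of the package's printed tables)
toy_reference <- function() {
  data.frame(
    node = as.character(1:15),
    degree = c(1, 1, 6, 2, 3, 5, 2, 3, 3, 5, 1, 3, 1, 1, 1),
    eigenvector_3dp = c(0.299, 0.299, 1, 0.518, 0.730, 0.919, 0.575, 0.491,
                        0.334, 0.388, 0.116, 0.238, 0.116, 0.275, 0.071),
    closeness_3dp = c(0.022, 0.022, 0.030, 0.022, 0.028, 0.036, 0.027, 0.034,
                      0.029, 0.030, 0.022, 0.023, 0.022, 0.024, 0.018),
    betweenness = c(0, 0, 31, 0, 4.5, 55.5, 0, 48, 9, 34, 0, 13, 0, 0, 0),
    heatmap_3dp = c(13, 13, -6.667, 10.5, 0.667, -7.2, 6.5, -3, 0, -6.8, 13,
                    1.667, 13, 13, 13),
    stringsAsFactors = FALSE
  )
}

# deterministic simple graph realising a graphical degree sequence
havel_hakimi_graph <- function(deg_seq) {
  n <- length(deg_seq)
  residual <- as.integer(deg_seq)
  edges <- list()
  repeat {
    ord <- order(residual, decreasing = TRUE)
    v <- ord[1L]
    d <- residual[v]
    if (d == 0L) break
    targets <- ord[2L:(d + 1L)]
    if (length(targets) < d || any(residual[targets] <= 0L)) {
      stop("degree sequence is not graphical")
    }
    edges[[length(edges) + 1L]] <- cbind(v, targets)
    residual[v] <- 0L
    residual[targets] <- residual[targets] - 1L
  }
  graph_from_edges(do.call(rbind, edges))
}
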