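#' Simple undirected graphs
#'
#' A `netgraph` is a simple (no loops, no multi-edges), undirected, unweighted
#' graph stored as an adjacency list over integer node indices, with the
#' original node labels kept alongside. Labels may be integers or strings;
#' node order is ascending label (numeric order when every label parses as a
#' number, lexicographic otherwise), which fixes the deterministic iteration
#' and tie-breaking order used throughout the package.
#'
#' @param edges a two-column matrix or data frame of edge endpoints (node
#'   labels), one row per edge.
#' @param simplify if `TRUE`, self-loops and duplicate edges are dropped
#'   silently (and counted in the `simplified` attribute); if `FALSE` they
#'   raise an error.
#' @return an object of class `netgraph` with components `labels` (node
#'   labels in canonical order), `adj` (list of integer neighbour indices),
#'   `N` (node count) and `M` (edge count).
#' @examples
#' g <- graph_from_edges(cbind(c(1, 2, 3), c(2, 3, 1)))
#' g$N
#' @export
graph_from_edges <- function(edges, simplify = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("'edges' must have at least two columns")
  if (nrow(edges) == 0L) stop("'edges' is empty: a graph needs at least one node")
  from <- trimws(as.character(edges[, 1L]))
  to   <- trimws(as.character(edges[, 2L]))
  labels <- sort_labels(unique(c(from, to)))
  i <- match(from, labels)
  j <- match(to, labels)

  loops <- i == j
  if (any(loops) && !simplify) {
    stop(sprintf("self-loop at node '%s' (use simplify = TRUE to drop)",
                 labels[i[which(loops)[1L]]]))
  }
  lo <- pmin(i, j)[!loops]
  hi <- pmax(i, j)[!loops]
  key <- paste(lo, hi)
  dup <- duplicated(key)
  if (any(dup) && !simplify) {
    stop(sprintf("duplicate edge %s-%s (use simplify = TRUE to collapse)",
                 labels[lo[which(dup)[1L]]], labels[hi[which(dup)[1L]]]))
  }
  lo <- lo[!dup]
  hi <- hi[!dup]

  n <- length(labels)
  adj <- build_adj(n, lo, hi)
  structure(
    list(labels = labels, adj = adj, N = n, M = length(lo)),
    simplified = c(loops = sum(loops), duplicates = sum(dup)),
    class = "netgraph"
  )
}

# canonical label order: numeric when all labels parse as numbers
sort_labels <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x, method = "radix")
}

# adjacency list from deduplicated index pairs (lo < hi)
build_adj <- function(n, lo, hi) {
  ends <- c(lo, hi)
  other <- c(hi, lo)
  adj <- split(other, factor(ends, levels = seq_len(n)))
  lapply(adj, function(v) sort(as.integer(v)))
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("netgraph: %d nodes, %d edges\n", x$N, x$M))
  shown <- utils::head(x$labels, 10L)
  cat("  nodes:", paste(shown, collapse = " "),
      if (x$N > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.netgraph <- function(object, ...) {
  deg <- degrees(object)
  res <- list(
    N = object$N, M = object$M,
    density = if (object$N >= 2L) graph_density(object) else NA_real_,
    degree_range = range(deg),
    connected = is_connected(object)
  )
  class(res) <- "summary.netgraph"
  res
}

#' @export
print.summary.netgraph <- function(x, ...) {
  cat(sprintf("netgraph: N = %d, M = %d, density = %s, degree %d..%d, %s\n",
              x$N, x$M, format(x$density, digits = 4),
              x$degree_range[1L], x$degree_range[2L],
              if (x$connected) "connected" else "disconnected"))
  invisible(x)
}

#' Node labels and degrees
#'
#' @param g a `netgraph`.
#' @return `node_ids()` returns the node labels in canonical order;
#'   `degrees()` a named integer vector of node degrees.
#' @export
node_ids <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  g$labels
}

#' @rdname node_ids
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  d <- vapply(g$adj, length, integer(1L))
  names(d) <- g$labels
  d
}

#' Edge density of a graph
#'
#' The fraction of possible edges present, 2M / (N (N - 1)).
#'
#' @param g a `netgraph` with at least two nodes.
#' @return a number in \[0, 1\].
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  if (g$N < 2L) stop("density undefined for a graph with fewer than 2 nodes")
  2 * g$M / (g$N * (g$N - 1))
}

#' Edge matrix of a graph
#'
#' @param g a `netgraph`.
#' @return a two-column character matrix of edges (each unordered pair once,
#'   smaller index first).
#' @export
edge_matrix <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  lo <- integer(0); hi <- integer(0)
  for (v in seq_len(g$N)) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]
    lo <- c(lo, rep.int(v, length(nb)))
    hi <- c(hi, nb)
  }
  cbind(from = g$labels[lo], to = g$labels[hi])
}

# internal: index of a node label, with a clear error
node_index <- function(g, v) {
  i <- match(trimws(as.character(v)), g$labels)
  if (anyNA(i)) stop(sprintf("node '%s' not in graph", as.character(v)[which(is.na(i))[1L]]))
  i
}
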