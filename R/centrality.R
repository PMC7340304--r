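#' Centrality vectors
#'
#' All centrality functions return a `centrality` object: a numeric vector of
#' per-node scores named by node label, carrying the measure name and its
#' ranking direction. For degree, eigenvector, closeness and betweenness a
#' higher score means a more influential node; for the heatmap centrality a
#' more negative score means a more influential node.
#'
#' @name centrality
#' @seealso [rank_nodes()], [all_centralities()]
NULL

new_centrality <- function(values, labels, measure,
                           direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  names(values) <- labels
  structure(values, measure = measure, direction = direction,
            class = c("centrality", "numeric"))
}

#' @export
print.centrality <- function(x, ...) {
  cat(sprintf("%s centrality (%s score = more influential) for %d nodes\n",
              attr(x, "measure"),
              if (attr(x, "direction") == "higher") "higher" else "more negative",
              length(x)))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Degree centrality
#'
#' The number of edges incident to each node: a purely local measure of
#' connectedness.
#'
#' @param g a `netgraph`.
#' @return a [centrality] vector (direction: higher is more influential).
#' @examples
#' degree_centrality(toy_network())
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  new_centrality(as.numeric(degrees(g)), g$labels, "degree")
}

#' Eigenvector centrality
#'
#' The dominant eigenvector of the adjacency matrix, rescaled so the maximum
#' entry is exactly 1, computed by power iteration from a uniform positive
#' start vector. A node scores highly when its neighbours score highly. On a
#' connected graph the dominant eigenvector is unique and positive
#' (Perron-Frobenius). The iteration runs on the shifted operator A + I,
#' which has the same dominant eigenvector but cannot oscillate on bipartite
#' graphs, where +/- lambda_max are both eigenvalues of A.
#'
#' @param g a connected `netgraph`.
#' @param tol convergence threshold on the max-norm change of the normalised
#'   vector between iterations.
#' @param max_iter iteration cap.
#' @return a [centrality] vector with attributes `lambda_max` (dominant
#'   eigenvalue of A) and `iterations`.
#' @export
eigenvector_centrality <- function(g, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(g, "netgraph"))
  if (!is_connected(g)) {
    stop("eigenvector centrality requires a connected graph")
  }
  adj <- g$adj
  x <- rep.int(1, g$N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y <- vapply(adj, function(nb) sum(x[nb]), numeric(1L)) + x  # (A + I) x
    y <- y / max(y)
    resid <- max(abs(y - x))
    x <- y
    if (resid <= tol) break
    if (iter >= max_iter) {
      stop(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
                   max_iter, resid))
    }
  }
  ax <- vapply(adj, function(nb) sum(x[nb]), numeric(1L))
  lambda <- sum(ax * x) / sum(x * x)  # Rayleigh quotient for A
  out <- new_centrality(x / max(x), g$labels, "eigenvector")
  attr(out, "lambda_max") <- lambda
  attr(out, "iterations") <- iter
  out
}

#' Closeness centrality
#'
#' The reciprocal of farness: 1 over the sum of shortest-path distances to
#' every other node. Unnormalised (no N - 1 factor).
#'
#' @param g a connected `netgraph` with at least two nodes.
#' @return a [centrality] vector with values in (0, 1].
#' @export
closeness_centrality <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  if (g$N < 2L) stop("closeness undefined for a single-node graph")
  new_centrality(1 / all_farness(g), g$labels, "closeness")
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' The sum over unordered node pairs \{j, k\} (endpoints excluded) of the
#' fraction of shortest j-k paths passing through the node. Computed with
#' Brandes' two-phase algorithm: an augmented BFS per source counts shortest
#' paths, then dependencies are accumulated in reverse BFS order. Each
#' unordered pair is counted once. Disconnected graphs are allowed;
#' unreachable pairs contribute nothing.
#'
#' @param g a `netgraph`.
#' @return a [centrality] vector of non-negative scores.
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  adj <- g$adj
  n <- g$N
  cb <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    visited <- integer(0)
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      visited <- c(visited, frontier)
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- cand[is.na(dist[cand])]
      d <- d + 1L
      dist[nxt] <- d
      for (w in nxt) {
        nb <- adj[[w]]
        pred <- nb[!is.na(dist[nb]) & dist[nb] == d - 1L]
        sigma[w] <- sum(sigma[pred])
      }
      frontier <- nxt
    }
    delta <- numeric(n)
    for (w in rev(visited)) {
      if (w == s) next
      nb <- adj[[w]]
      pred <- nb[!is.na(dist[nb]) & dist[nb] == dist[w] - 1L]
      delta[pred] <- delta[pred] + (sigma[pred] / sigma[w]) * (1 + delta[w])
    }
    delta[s] <- 0
    cb <- cb + delta
  }
  # each unordered pair was accumulated from both endpoints as source
  new_centrality(cb / 2, g$labels, "betweenness")
}

#' Heatmap centrality
#'
#' Scores each node by its farness minus the arithmetic mean of its
#' neighbours' farness:
#' \deqn{C_{HM}(v) = F(v) - \frac{1}{\deg(v)} \sum_{u \in adj(v)} F(u)}
#' where \eqn{F(v)} is the sum of shortest-path distances from \eqn{v} to
#' every other node. A node whose farness is smaller than the average of its
#' neighbours' — a strongly negative score — is a "hot spot": shortest paths
#' between many pairs are likely to pass through it rather than around it,
#' which is the signature of a super-spreader. All farness values are
#' computed in one all-pairs BFS sweep (O(N(N+M))) and reused for every
#' neighbour average.
#'
#' @param g a connected `netgraph` with at least two nodes (so every node
#'   has degree >= 1).
#' @return a [centrality] vector; direction is "lower": more negative means
#'   more influential.
#' @examples
#' hm <- heatmap_centrality(toy_network())
#' hm["6"]   # most influential node in the toy network
#' @export
heatmap_centrality <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  deg <- vapply(g$adj, length, integer(1L))
  if (any(deg == 0L)) {
    stop("heatmap centrality undefined for isolated (degree-0) nodes")
  }
  far <- all_farness(g)  # errors on a disconnected graph
  hm <- far - vapply(g$adj, function(nb) mean(far[nb]), numeric(1L))
  new_centrality(hm, g$labels, "heatmap", direction = "lower")
}

#' Compute one centrality measure by name
#'
#' @param g a `netgraph`.
#' @param measure one of `"degree"`, `"eigenvector"`, `"closeness"`,
#'   `"betweenness"`, `"heatmap"`.
#' @param ... passed to the underlying function.
#' @return a [centrality] vector.
#' @export
compute_centrality <- function(g, measure = c("degree", "eigenvector",
                                              "closeness", "betweenness",
                                              "heatmap"), ...) {
  measure <- match.arg(measure)
  switch(measure,
         degree      = degree_centrality(g),
         eigenvector = eigenvector_centrality(g, ...),
         closeness   = closeness_centrality(g),
         betweenness = betweenness_centrality(g),
         heatmap     = heatmap_centrality(g))
}

#' All five centralities in one pass
#'
#' Computes degree, eigenvector, closeness, betweenness and heatmap
#' centrality, sharing a single all-pairs BFS sweep between closeness and
#' heatmap.
#'
#' @param g a connected `netgraph`.
#' @param measures subset of measure names to compute.
#' @return a data frame with a `node` column and one column per measure,
#'   nodes in canonical label order; the full [centrality] objects are
#'   attached as the `"vectors"` attribute (a named list).
#' @examples
#' head(all_centralities(toy_network()))
#' @export
all_centralities <- function(g, measures = c("degree", "eigenvector",
                                             "closeness", "betweenness",
                                             "heatmap")) {
  stopifnot(inherits(g, "netgraph"))
  measures <- match.arg(measures, several.ok = TRUE)
  vecs <- list()
  far <- NULL
  for (ms in measures) {
    if (ms %in% c("closeness", "heatmap") && is.null(far)) {
      far <- all_farness(g)
    }
    vecs[[ms]] <- switch(ms,
      degree      = degree_centrality(g),
      eigenvector = eigenvector_centrality(g),
      closeness   = new_centrality(1 / far, g$labels, "closeness"),
      betweenness = betweenness_centrality(g),
      heatmap     = {
        deg <- vapply(g$adj, length, integer(1L))
        if (any(deg == 0L)) stop("heatmap centrality undefined for isolated nodes")
        hm <- far - vapply(g$adj, function(nb) mean(far[nb]), numeric(1L))
        new_centrality(hm, g$labels, "heatmap", direction = "lower")
      })
  }
  out <- data.frame(node = g$labels, stringsAsFactors = FALSE)
  for (ms in measures) out[[ms]] <- as.numeric(vecs[[ms]])
  attr(out, "vectors") <- vecs
  out
}

#' Round half away from zero
#'
#' Decimal rounding where .5 cases move away from zero (so -6.6665 at three
#' decimals gives -6.667), the convention used when printing centrality
#' tables. Base R's `round()` rounds half to even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
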