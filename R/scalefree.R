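#' Generate a Barabasi-Albert scale-free network
#'
#' Growth with linear preferential attachment. The network starts from a
#' single node; each arriving node connects to `min(m, existing)` *distinct*
#' existing nodes, drawn without replacement with probability proportional
#' to current degree (sequential draws with renormalisation; uniformly when
#' every candidate still has degree 0, which happens only at the first
#' attachment). The arriving node is never a candidate for its own edges.
#' The result is always simple and connected, and its edge count is the
#' deterministic \eqn{M = m (N - 1) - m (m - 1) / 2} whenever \eqn{N - 1 \ge
#' m}, so the mean degree 2M/N is seed-independent. With `m = 1` the result
#' is a uniform-attachment-free preferential tree.
#'
#' @param N number of nodes (>= 2).
#' @param m edges added per arriving node (>= 1).
#' @param rng_seed integer seed; `NULL` uses the current RNG state.
#' @return a `netgraph` with nodes labelled "1".."N" in arrival order.
#' @examples
#' g <- generate_ba(100, 2, rng_seed = 1)
#' g$M  # 2 * 99 - 1
#' @export
generate_ba <- function(N, m, rng_seed = NULL) {
  if (N < 2L) stop("'N' must be at least 2")
  if (m < 1L) stop("'m' must be at least 1")
  if (!is.null(rng_seed)) set.seed(rng_seed %% 2147483647L)
  N <- as.integer(N)
  m <- as.integer(m)
  n_edges <- sum(pmin(m, seq_len(N - 1L)))
  lo <- integer(n_edges)
  hi <- integer(n_edges)
  deg <- integer(N)
  pos <- 0L
  for (v in 2:N) {
    n_exist <- v - 1L
    k <- min(m, n_exist)
    dv <- deg[seq_len(n_exist)]
    targets <- if (sum(dv) == 0L) {
      sample.int(n_exist, k)
    } else {
      sample.int(n_exist, k, replace = FALSE, prob = dv)
    }
    lo[pos + seq_len(k)] <- targets
    hi[pos + seq_len(k)] <- v
    pos <- pos + k
    deg[targets] <- deg[targets] + 1L
    deg[v] <- k
  }
  structure(list(labels = as.character(seq_len(N)),
                 adj = build_adj(N, lo, hi),
                 N = N, M = n_edges),
            class = "netgraph")
}

#' Attachment parameter for a target density
#'
#' For a Barabasi-Albert network of size N the density is approximately
#' 2m/N, so a target density d is achieved with m = round(d N / 2).
#'
#' @param N node count.
#' @param d target edge density.
#' @return the integer m (>= 1).
#' @examples
#' m_for_density(3000, 0.006)  # 9
#' @export
m_for_density <- function(N, d) {
  m <- as.integer(round(d * N / 2))
  if (m < 1L) stop(sprintf("density %g is too low for N = %d (m would be < 1)", d, N))
  m
}

#' Clustering coefficient
#'
#' `"global"` is the transitivity ratio, 3 x (number of triangles) /
#' (number of connected triples). `"mean-local"` averages each node's local
#' triangle density (neighbour pairs that are themselves adjacent); nodes
#' with degree < 2 contribute 0.
#'
#' @param g a `netgraph`.
#' @param kind `"global"` (default) or `"mean-local"`.
#' @return a fraction in \[0, 1\]; 0 for a graph with no connected triples.
#' @export
clustering_coefficient <- function(g, kind = c("global", "mean-local")) {
  stopifnot(inherits(g, "netgraph"))
  kind <- match.arg(kind)
  adj <- g$adj
  deg <- vapply(adj, length, integer(1L))
  # per-node count of adjacent neighbour pairs (= triangles through the node)
  tri <- vapply(seq_len(g$N), function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2L) return(0)
    sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), numeric(1L))) / 2
  }, numeric(1L))
  if (kind == "global") {
    triples <- sum(deg * (deg - 1) / 2)
    if (triples == 0) return(0)
    sum(tri) / triples  # = 3 * (#triangles) / (#triples); each triangle counted at 3 nodes
  } else {
    local <- ifelse(deg < 2L, 0, tri / (deg * (deg - 1) / 2))
    mean(local)
  }
}

#' Ensemble structural summary of Barabasi-Albert networks
#'
#' Generates `replicates` independent networks with the given (N, m) and
#' reports the mean and standard deviation of the average degree 2M/N, the
#' clustering coefficient and the diameter across the ensemble.
#'
#' @param N,m Barabasi-Albert parameters, as in [generate_ba()].
#' @param replicates how many networks to generate.
#' @param rng_seed integer base seed; replicate i uses `rng_seed + i`.
#' @param clustering `"global"` or `"mean-local"` (see
#'   [clustering_coefficient()]).
#' @return an object of class `structural_summary`: a list with `per_replicate`
#'   (data frame of mean_degree, clustering, diameter per realisation) and
#'   `summary` (mean and sd of each), plus the generating parameters.
#' @export
structural_summary <- function(N, m, replicates = 10L, rng_seed = 1L,
                               clustering = c("global", "mean-local")) {
  clustering <- match.arg(clustering)
  rows <- lapply(seq_len(replicates), function(i) {
    g <- generate_ba(N, m, rng_seed = rng_seed + i)
    data.frame(replicate = i,
               mean_degree = 2 * g$M / g$N,
               clustering = clustering_coefficient(g, clustering),
               diameter = graph_diameter(g))
  })
  per <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("mean_degree", "clustering", "diameter"),
    mean = c(mean(per$mean_degree), mean(per$clustering), mean(per$diameter)),
    sd = c(stats::sd(per$mean_degree), stats::sd(per$clustering),
           stats::sd(per$diameter))
  )
  if (replicates == 1L) summ$sd <- 0
  structure(list(N = N, m = m, replicates = replicates,
                 clustering_kind = clustering,
                 per_replicate = per, summary = summ),
            class = "structural_summary")
}

#' @export
print.structural_summary <- function(x, ...) {
  cat(sprintf("Barabasi-Albert ensemble: N = %d, m = %d, %d replicate(s)\n",
              x$N, x$m, x$replicates))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %g +/- %g\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Log-log power-law fit of the degree distribution
#'
#' Fits log P(k) ~ -gamma log k by ordinary least squares over the degrees k
#' with non-zero empirical frequency P(k) = (#nodes of degree k)/N (degree-0
#' nodes cannot enter the log fit). A scale-free network has gamma > 1. Note
#' this is the descriptive log-log regression, not a maximum-likelihood
#' tail fit.
#'
#' @param g a `netgraph` with at least 3 distinct positive degrees.
#' @return an object of class `power_law_fit`: a list with `gamma`,
#'   `r_squared`, `k` and `p_k` (the support of the fit), and the underlying
#'   `lm` fit.
#' @export
fit_power_law <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  deg <- degrees(g)
  tab <- table(deg[deg > 0L])
  k <- as.numeric(names(tab))
  p_k <- as.numeric(tab) / g$N
  if (length(k) < 3L) {
    stop(sprintf("need at least 3 distinct positive degrees to fit (got %d)",
                 length(k)))
  }
  fit <- stats::lm(log(p_k) ~ log(k))
  structure(list(
    gamma = -unname(stats::coef(fit)[2L]),
    r_squared = summary(fit)$r.squared,
    k = k, p_k = p_k, fit = fit
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law degree fit: P(k) ~ k^-%.3f  (R^2 = %.3f, %d support points)\n",
              x$gamma, x$r_squared, length(x$k)))
  invisible(x)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  plot(log(x$k), log(x$p_k), xlab = "log k", ylab = "log P(k)", ...)
  graphics::abline(x$fit, lty = 2)
  invisible(x)
}
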