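#' Per-node centrality table with ranks
#'
#' The worked-example layout: one row per node with each selected measure's
#' value and its rank (label-broken ties).
#'
#' @param g a connected `netgraph`.
#' @param measures subset of measure names.
#' @return a data frame with `node` plus `<measure>` and `<measure>_rank`
#'   columns, nodes in canonical order.
#' @examples
#' centrality_table(toy_network(), c("betweenness", "heatmap"))
#' @export
centrality_table <- function(g, measures = c("degree", "eigenvector",
                                             "closeness", "betweenness",
                                             "heatmap")) {
  tbl <- all_centralities(g, measures)
  vecs <- attr(tbl, "vectors")
  for (ms in measures) {
    rt <- rank_nodes(vecs[[ms]], tie_method = "id")
    tbl[[paste0(ms, "_rank")]] <- rt$tentative[match(tbl$node, rt$node)]
  }
  ord <- c("node", as.vector(rbind(measures, paste0(measures, "_rank"))))
  tbl[, ord]
}

#' Rank-correlation matrices across measures
#'
#' Computes Spearman's rho and the decided-pairs Kendall tau for every pair
#' of the selected measures.
#'
#' @param g a connected `netgraph`.
#' @param measures subset of measure names (>= 2).
#' @param tie_method passed to [rank_nodes()].
#' @return a list with symmetric matrices `rho` and `tau` (unit diagonal).
#' @examples
#' rank_compare(toy_network(), c("betweenness", "heatmap"))
#' @export
rank_compare <- function(g, measures = c("degree", "eigenvector", "closeness",
                                         "betweenness", "heatmap"),
                         tie_method = "id") {
  if (length(measures) < 2L) stop("need at least two measures to compare")
  vecs <- attr(all_centralities(g, measures), "vectors")
  ranks <- lapply(vecs, rank_nodes, tie_method = tie_method)
  p <- length(measures)
  rho <- tau <- matrix(1, p, p, dimnames = list(measures, measures))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      rho[i, j] <- rho[j, i] <- spearman_rank(ranks[[i]], ranks[[j]])$rho
      tau[i, j] <- tau[j, i] <- kendall_rank(ranks[[i]], ranks[[j]])$tau
    }
  }
  list(rho = rho, tau = tau)
}

#' Top-k table across measures
#'
#' @param g a connected `netgraph`.
#' @param k list length.
#' @param measures subset of measure names.
#' @return a data frame with column `rank` (1..k) and one column of node
#'   labels per measure.
#' @export
topk_table <- function(g, k = 10L, measures = c("degree", "eigenvector",
                                                "closeness", "betweenness",
                                                "heatmap")) {
  if (k > g$N) stop(sprintf("k = %d exceeds node count %d", k, g$N))
  vecs <- attr(all_centralities(g, measures), "vectors")
  out <- data.frame(rank = seq_len(k))
  for (ms in measures) out[[ms]] <- top_nodes(vecs[[ms]], k)
  out
}

#' CPU-time benchmark of betweenness vs heatmap
#'
#' Times the full-graph computation of the selected measures on
#' Barabasi-Albert networks over a grid of sizes and densities. Elapsed
#' processor time is user + system time from `proc.time()`. The records are
#' informational: absolute times depend on hardware.
#'
#' @param N_values vector of network sizes.
#' @param densities vector of target densities (mapped to m via
#'   [m_for_density()]).
#' @param measures measures to time.
#' @param replicates networks per (N, d) cell.
#' @param rng_seed base seed.
#' @return a data frame of timing records: N, density, m, M, replicate,
#'   measure, cpu_seconds.
#' @export
benchmark_centralities <- function(N_values, densities,
                                   measures = c("betweenness", "heatmap"),
                                   replicates = 3L, rng_seed = 1L) {
  rows <- list()
  run <- 0L
  for (N in N_values) {
    for (d in densities) {
      m <- m_for_density(N, d)
      for (r in seq_len(replicates)) {
        run <- run + 1L
        g <- generate_ba(N, m, rng_seed = rng_seed + run)
        for (ms in measures) {
          t0 <- proc.time()
          compute_centrality(g, ms)
          dt <- proc.time() - t0
          rows[[length(rows) + 1L]] <- data.frame(
            N = N, density = d, m = m, M = g$M, replicate = r,
            measure = ms,
            cpu_seconds = unname(dt["user.self"] + dt["sys.self"]))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment: the command name, its
#' parameters, the seed, and package/R versions, as JSON.
#'
#' @param path output file.
#' @param command experiment name.
#' @param params named list of parameters (must be JSON-serialisable).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params) {
  manifest <- list(
    command = command,
    params = params,
    package = "heatnet",
    package_version = as.character(utils::packageVersion("heatnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest file written by [write_manifest()].
#' @return the manifest as a list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
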