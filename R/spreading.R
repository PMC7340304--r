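#' One synchronous step of the modified SI process
#'
#' In the modified susceptible-infected dynamics, at each time step every
#' node infected at the *start* of the step picks one of its currently
#' susceptible neighbours uniformly at random (if it has any) and infects it
#' with probability `beta`. Updates are synchronous: nodes infected during
#' the step do not transmit until the next step, so the result does not
#' depend on the order in which infectors are visited. Two infectors may
#' pick the same target; it simply becomes infected once.
#'
#' Uses R's current random number stream.
#'
#' @param g a `netgraph`.
#' @param infected character vector of currently infected node labels.
#' @param beta per-contact infection probability in \[0, 1\].
#' @return character vector of newly infected node labels (possibly empty).
#' @examples
#' g <- toy_network()
#' set.seed(1)
#' si_step(g, infected = "6", beta = 1)
#' @export
si_step <- function(g, infected, beta = 1) {
  stopifnot(inherits(g, "netgraph"))
  if (length(infected) == 0L) stop("'infected' must be non-empty")
  inf <- rep.int(FALSE, g$N)
  inf[node_index(g, infected)] <- TRUE
  g$labels[si_step_idx(g$adj, inf, beta)]
}

# internal: index-level step; inf is a logical vector over node indices
si_step_idx <- function(adj, inf, beta) {
  targets <- integer(0)
  for (i in which(inf)) {
    sus <- adj[[i]][!inf[adj[[i]]]]
    if (length(sus) == 0L) next
    pick <- if (length(sus) == 1L) sus else sus[sample.int(length(sus), 1L)]
    if (beta >= 1 || stats::runif(1L) < beta) targets <- c(targets, pick)
  }
  unique(targets)
}

#' Run the modified SI spreading process
#'
#' Simulates the synchronous SI dynamics (see [si_step()]) from a seed set,
#' repeated over independent replicates, and reports the per-step mean and
#' standard deviation of the cumulative number of infected nodes F(t).
#' F(0) equals the seed count; a run stops as soon as no susceptible nodes
#' remain. `t_c` is the first step at which every replicate has no
#' susceptible nodes left (or `t_max` if some replicate never finishes).
#' Replicate r uses its own RNG stream seeded with `rng_seed + r`, so any
#' single replicate is reproducible in isolation.
#'
#' @param g a connected `netgraph`.
#' @param seeds non-empty vector of initially infected node labels.
#' @param beta per-contact infection probability (default 1).
#' @param replicates number of independent runs (default 100).
#' @param t_max step cap; default N, enough for certain termination when
#'   `beta = 1` on a connected graph.
#' @param rng_seed integer seed; `NULL` uses the current RNG state (one
#'   stream for all replicates).
#' @return an object of class `spread_curve`: a data frame with columns `t`,
#'   `mean_F`, `sd_F` for t = 0..t_c, with attributes `t_c`, `replicates`,
#'   `beta`, `seeds` and `N`.
#' @examples
#' run_si(toy_network(), seeds = c("6", "10"), replicates = 20, rng_seed = 1)
#' @export
run_si <- function(g, seeds, beta = 1, replicates = 100L, t_max = NULL,
                   rng_seed = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (length(seeds) == 0L) stop("'seeds' must be non-empty")
  if (beta < 0 || beta > 1) stop("'beta' must be in [0, 1]")
  if (replicates < 1L) stop("'replicates' must be >= 1")
  seed_idx <- node_index(g, seeds)
  if (is.null(t_max)) t_max <- g$N
  adj <- g$adj
  n <- g$N
  Fmat <- matrix(NA_real_, nrow = replicates, ncol = t_max + 1L)
  done_at <- rep.int(t_max, replicates)
  for (r in seq_len(replicates)) {
    if (!is.null(rng_seed)) set.seed((rng_seed + r) %% 2147483647L)
    inf <- rep.int(FALSE, n)
    inf[seed_idx] <- TRUE
    Fmat[r, 1L] <- sum(inf)
    for (t in seq_len(t_max)) {
      if (all(inf)) {
        done_at[r] <- t - 1L
        Fmat[r, (t + 1L):(t_max + 1L)] <- n
        break
      }
      new <- si_step_idx(adj, inf, beta)
      inf[new] <- TRUE
      Fmat[r, t + 1L] <- sum(inf)
      if (t == t_max && all(inf)) done_at[r] <- t
    }
  }
  t_c <- max(done_at)
  steps <- 0L:t_c
  curve <- data.frame(
    t = steps,
    mean_F = colMeans(Fmat[, steps + 1L, drop = FALSE]),
    sd_F = apply(Fmat[, steps + 1L, drop = FALSE], 2L, stats::sd)
  )
  structure(curve, t_c = t_c, replicates = replicates, beta = beta,
            seeds = g$labels[seed_idx], N = n,
            class = c("spread_curve", "data.frame"))
}

#' @export
print.spread_curve <- function(x, ...) {
  cat(sprintf(
    "SI spread curve: %d seed(s), beta = %g, %d replicate(s), t_c = %d, F(t_c) = %g of %d\n",
    length(attr(x, "seeds")), attr(x, "beta"), attr(x, "replicates"),
    attr(x, "t_c"), x$mean_F[nrow(x)], attr(x, "N")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.spread_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$t, x$mean_F, type = "l", col = col,
         xlab = "time step t", ylab = "mean F(t)",
         ylim = c(0, attr(x, "N")), ...)
  } else {
    graphics::lines(x$t, x$mean_F, col = col, ...)
  }
  graphics::arrows(x$t, x$mean_F - x$sd_F, x$t, x$mean_F + x$sd_F,
                   angle = 90, code = 3, length = 0.02, col = col)
  invisible(x)
}

#' Spreading capability of each measure's top-k nodes
#'
#' For each centrality measure, its top-k nodes (label-broken ties)
#' collectively seed the modified SI process; the resulting mean F(t) curves
#' measure how well each measure's most influential nodes spread.
#'
#' @param g a connected `netgraph`.
#' @param centralities a named list of [centrality] vectors on `g` (e.g.
#'   `attr(all_centralities(g), "vectors")`).
#' @param k seed-set size (top-k nodes per measure).
#' @param ... passed to [run_si()] (`beta`, `replicates`, `t_max`,
#'   `rng_seed`).
#' @return a named list of [run_si()] curves, class `spread_comparison`.
#' @export
spreading_capability <- function(g, centralities, k, ...) {
  stopifnot(inherits(g, "netgraph"), length(centralities) > 0L)
  if (is.null(names(centralities))) {
    names(centralities) <- vapply(centralities, attr, character(1L), "measure")
  }
  out <- lapply(centralities, function(cv) {
    run_si(g, seeds = top_nodes(cv, k), ...)
  })
  class(out) <- "spread_comparison"
  out
}

#' @export
print.spread_comparison <- function(x, ...) {
  for (ms in names(x)) {
    cv <- x[[ms]]
    cat(sprintf("%-12s t_c = %3d  F(t_c) = %g\n", ms,
                attr(cv, "t_c"), cv$mean_F[nrow(cv)]))
  }
  invisible(x)
}

#' @export
plot.spread_comparison <- function(x, ...) {
  cols <- seq_along(x)
  for (i in cols) plot(x[[i]], add = i > 1L, col = cols[i], ...)
  graphics::legend("bottomright", legend = names(x), col = cols, lty = 1)
  invisible(x)
}
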