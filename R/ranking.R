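#' Rank nodes by a centrality measure
#'
#' Nodes are sorted in decreasing order of influence (decreasing score, or
#' increasing score for the heatmap measure, whose most negative value is
#' most influential). The position in that order is the *tentative* rank,
#' with ties between equal scores broken in favour of the smaller node label.
#' The *final* rank depends on the tie rule:
#' \describe{
#'   \item{`"id"`}{final rank = tentative rank (ties stay distinct, decided
#'     by node label). This is the rule used in worked rank-correlation
#'     examples and for top-k lists.}
#'   \item{`"average"`}{nodes with equal scores share the mean of their
#'     tentative ranks (the textbook mid-rank rule).}
#' }
#'
#' @param cv a [centrality] vector.
#' @param tie_method `"id"` (default) or `"average"`.
#' @return an object of class `rank_table`: a data frame with columns
#'   `node`, `value`, `tentative` (integer permutation of 1..N) and `final`,
#'   ordered by rank, with attributes `measure` and `tie_method`.
#' @examples
#' rank_nodes(betweenness_centrality(toy_network()))
#' @export
rank_nodes <- function(cv, tie_method = c("id", "average")) {
  stopifnot(inherits(cv, "centrality"))
  tie_method <- match.arg(tie_method)
  values <- as.numeric(cv)
  labels <- names(cv)
  key <- if (attr(cv, "direction") == "lower") values else -values
  # labels are already in canonical order, so order() ties fall to smaller label
  ord <- order(key)
  tentative <- integer(length(ord))
  tentative[ord] <- seq_along(ord)
  final <- if (tie_method == "id") {
    as.numeric(tentative)
  } else {
    stats::ave(as.numeric(tentative), match(values, values), FUN = mean)
  }
  out <- data.frame(node = labels, value = values,
                    tentative = tentative, final = final,
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, measure = attr(cv, "measure"), tie_method = tie_method,
            class = c("rank_table", "data.frame"))
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("node ranking by %s centrality (ties: %s)\n",
              attr(x, "measure"), attr(x, "tie_method")))
  print.data.frame(x, ...)
  invisible(x)
}

# align two rank tables on the same node set; returns final ranks side by side
align_ranks <- function(r1, r2) {
  stopifnot(inherits(r1, "rank_table"), inherits(r2, "rank_table"))
  if (!setequal(r1$node, r2$node)) {
    stop("rank tables cover different node sets")
  }
  i <- match(r1$node, r2$node)
  list(node = r1$node, a = r1$final, b = r2$final[i])
}

#' Spearman rank correlation between two node rankings
#'
#' Applies the classical rank-difference formula
#' \deqn{\rho = 1 - \frac{6 \sum_i d_i^2}{N (N^2 - 1)}}
#' where \eqn{d_i} is the difference between the two final ranks of node
#' \eqn{i}. With tie method `"id"` both rankings are permutations of 1..N
#' and the formula is exact.
#'
#' @param r1,r2 [rank_table] objects over the same node set.
#' @return an object of class `rank_correlation`: a list with `method`,
#'   `rho`, `sum_d_squared`, `n` and a `per_node` data frame (node, the two
#'   final ranks, `d`, `d_squared`).
#' @examples
#' g <- toy_network()
#' spearman_rank(rank_nodes(betweenness_centrality(g)),
#'               rank_nodes(heatmap_centrality(g)))
#' @export
spearman_rank <- function(r1, r2) {
  al <- align_ranks(r1, r2)
  d <- al$a - al$b
  n <- length(d)
  if (n < 2L) stop("need at least two nodes")
  rho <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  structure(list(
    method = "spearman",
    rho = rho,
    sum_d_squared = sum(d^2),
    n = n,
    measures = c(attr(r1, "measure"), attr(r2, "measure")),
    per_node = data.frame(node = al$node, rank_x = al$a, rank_y = al$b,
                          d = abs(d), d_squared = d^2,
                          stringsAsFactors = FALSE)
  ), class = "rank_correlation")
}

#' Kendall rank correlation between two node rankings
#'
#' Classifies every unordered node pair as concordant (ordered the same way
#' by both rankings), discordant (ordered oppositely) or neither (tied in at
#' least one ranking), then applies
#' \deqn{\tau = \frac{N_C - N_D}{N_C + N_D}.}
#' Note the denominator is the number of decided pairs, which differs from
#' both the tau-a and tau-b conventions when ties are present (see
#' [kendall_tau_b()]); with `"id"`-broken ranks there are no ties and all
#' three coincide with tau-a.
#'
#' @param r1,r2 [rank_table] objects over the same node set.
#' @return an object of class `rank_correlation`: a list with `method`,
#'   `tau`, `n_concordant`, `n_discordant`, `n_excluded_ties`, `n` and a
#'   `per_node` data frame giving, for nodes sorted by the first ranking,
#'   the concordant and discordant pair counts against the nodes ranked
#'   below them.
#' @export
kendall_rank <- function(r1, r2) {
  al <- align_ranks(r1, r2)
  n <- length(al$a)
  if (n < 2L) stop("need at least two nodes")
  ord <- order(al$a)
  a <- al$a[ord]
  b <- al$b[ord]
  nc <- integer(n)
  nd <- integer(n)
  ties <- 0L
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    da <- a[rest] - a[i]
    db <- b[rest] - b[i]
    s <- sign(da) * sign(db)
    nc[i] <- sum(s > 0)
    nd[i] <- sum(s < 0)
    ties <- ties + sum(s == 0)
  }
  n_c <- sum(nc)
  n_d <- sum(nd)
  if (n_c + n_d == 0L) {
    stop("all pairs are tied: Kendall correlation undefined")
  }
  structure(list(
    method = "kendall",
    tau = (n_c - n_d) / (n_c + n_d),
    n_concordant = n_c,
    n_discordant = n_d,
    n_excluded_ties = ties,
    n = n,
    measures = c(attr(r1, "measure"), attr(r2, "measure")),
    per_node = data.frame(node = al$node[ord], rank_x = a, rank_y = b,
                          n_concordant = nc, n_discordant = nd,
                          stringsAsFactors = FALSE)
  ), class = "rank_correlation")
}

#' Kendall tau-b for two node rankings
#'
#' The standard tie-corrected Kendall coefficient, provided for comparison
#' with the decided-pairs [kendall_rank()] statistic. Delegates to
#' `stats::cor(..., method = "kendall")` on the final ranks.
#'
#' @param r1,r2 [rank_table] objects over the same node set.
#' @return a single number in \[-1, 1\].
#' @export
kendall_tau_b <- function(r1, r2) {
  al <- align_ranks(r1, r2)
  stats::cor(al$a, al$b, method = "kendall")
}

#' @export
print.rank_correlation <- function(x, ...) {
  if (x$method == "spearman") {
    cat(sprintf("Spearman rho(%s, %s) = %.4f  (sum d^2 = %g, N = %d)\n",
                x$measures[1L], x$measures[2L], x$rho, x$sum_d_squared, x$n))
  } else {
    cat(sprintf("Kendall tau(%s, %s) = %.4f  (N_C = %d, N_D = %d, tied pairs = %d)\n",
                x$measures[1L], x$measures[2L], x$tau,
                x$n_concordant, x$n_discordant, x$n_excluded_ties))
  }
  invisible(x)
}

#' Top-k most influential nodes
#'
#' `top_nodes()` lists the k most influential nodes of a measure, in rank
#' order, under the label-broken ("id") tie rule. `topk_overlap()` counts
#' how many nodes two measures' top-k lists share.
#'
#' @param cv,a,b [centrality] vectors.
#' @param k how many nodes (k <= N).
#' @return `top_nodes()` a character vector of k node labels;
#'   `topk_overlap()` an integer count.
#' @examples
#' top_nodes(heatmap_centrality(toy_network()), 2)
#' @export
top_nodes <- function(cv, k) {
  stopifnot(inherits(cv, "centrality"))
  if (k > length(cv)) stop(sprintf("k = %d exceeds node count %d", k, length(cv)))
  rt <- rank_nodes(cv, tie_method = "id")
  rt$node[seq_len(k)]
}

#' @rdname top_nodes
#' @export
topk_overlap <- function(a, b, k) {
  length(intersect(top_nodes(a, k), top_nodes(b, k)))
}
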