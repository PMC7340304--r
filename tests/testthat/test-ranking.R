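test_that("ranking sorts by influence with label-broken ties", {
  g <- toy_network()
  rb <- rank_nodes(betweenness_centrality(g))
  expect_identical(rb$node,
                   as.character(c(6, 8, 10, 3, 12, 9, 5, 1, 2, 4, 7, 11, 13, 14, 15)))
  expect_identical(rb$tentative, 1:15)
  expect_identical(rb$final, as.numeric(1:15))

  rh <- rank_nodes(heatmap_centrality(g))
  expect_identical(rh$node[1:3], c("6", "10", "3"))
  # the six heatmap-13 leaves take ranks 10..15 in label order
  expect_identical(rh$node[10:15], as.character(c(1, 2, 11, 13, 14, 15)))
})

test_that("average tie rule assigns mid-ranks; id rule keeps distinct ranks", {
  k3 <- complete_graph(3)
  ra <- rank_nodes(degree_centrality(k3), tie_method = "average")
  expect_equal(ra$final, rep(2, 3))
  ri <- rank_nodes(degree_centrality(k3), tie_method = "id")
  expect_equal(sort(ri$final), as.numeric(1:3))
  # final ranks always sum to N(N+1)/2
  g <- toy_network()
  for (tm in c("id", "average")) {
    rt <- rank_nodes(betweenness_centrality(g), tie_method = tm)
    expect_equal(sum(rt$final), 15 * 16 / 2)
  }
  expect_error(rank_nodes(degree_centrality(k3), tie_method = "median"))
})

test_that("the worked betweenness-vs-heatmap example reproduces in full", {
  g <- toy_network()
  rb <- rank_nodes(betweenness_centrality(g))
  rh <- rank_nodes(heatmap_centrality(g))

  sp <- spearman_rank(rb, rh)
  expect_equal(sp$sum_d_squared, 30)
  expect_equal(round_half_away(sp$rho, 3), 0.946)
  # the per-node |d| column, nodes 1..15
  d <- sp$per_node$d[match(as.character(1:15), sp$per_node$node)]
  expect_equal(d, c(2, 2, 1, 1, 1, 0, 3, 2, 1, 1, 0, 2, 0, 0, 0))

  kd <- kendall_rank(rb, rh)
  expect_equal(kd$n_concordant, 96L)
  expect_equal(kd$n_discordant, 9L)
  expect_equal(round_half_away(kd$tau, 3), 0.829)
  expect_equal(kd$n_concordant + kd$n_discordant + kd$n_excluded_ties,
               15L * 14L / 2L)
  # per-node concordance table, rows sorted by betweenness rank
  expect_identical(kd$per_node$node,
                   as.character(c(6, 8, 10, 3, 12, 9, 5, 1, 2, 4, 7, 11, 13, 14, 15)))
  expect_equal(kd$per_node$n_concordant,
               c(14, 11, 12, 11, 8, 9, 8, 5, 4, 4, 4, 3, 2, 1, 0))
  expect_equal(kd$per_node$n_discordant,
               c(0, 2, 0, 0, 2, 0, 0, 2, 2, 1, 0, 0, 0, 0, 0))
})

test_that("degenerate correlations hit their closed forms", {
  g <- toy_network()
  rb <- rank_nodes(betweenness_centrality(g))
  expect_equal(spearman_rank(rb, rb)$rho, 1)
  expect_equal(kendall_rank(rb, rb)$tau, 1)
  # exact reversal of a tie-free ranking
  cv <- degree_centrality(path_graph(5))
  vals <- as.numeric(1:5)
  up <- structure(vals, names = as.character(1:5), measure = "up",
                  direction = "higher", class = c("centrality", "numeric"))
  down <- structure(rev(vals), names = as.character(1:5), measure = "down",
                    direction = "higher", class = c("centrality", "numeric"))
  expect_equal(spearman_rank(rank_nodes(up), rank_nodes(down))$rho, -1)
  expect_equal(kendall_rank(rank_nodes(up), rank_nodes(down))$tau, -1)
})

test_that("correlations agree with the standard-library oracles when tie-free", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1000, n)  # distinct scores: no ties
    y <- sample(1000, n)
    cx <- structure(as.numeric(x), names = as.character(1:n), measure = "x",
                    direction = "higher", class = c("centrality", "numeric"))
    cy <- structure(as.numeric(y), names = as.character(1:n), measure = "y",
                    direction = "higher", class = c("centrality", "numeric"))
    rx <- rank_nodes(cx); ry <- rank_nodes(cy)
    expect_equal(spearman_rank(rx, ry)$rho,
                 stats::cor(rx$final[match(1:n, rx$node)],
                            ry$final[match(1:n, ry$node)], method = "pearson"),
                 tolerance = 1e-12)
    expect_equal(kendall_rank(rx, ry)$tau,
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
    expect_equal(kendall_tau_b(rx, ry), stats::cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(kendall_rank(rx, ry)$tau, kendall_rank(ry, rx)$tau)
  }
})

test_that("strictly monotone transforms leave ranks and correlations unchanged", {
  g <- toy_network()
  cb <- betweenness_centrality(g)
  hm <- heatmap_centrality(g)
  cb2 <- structure(exp(as.numeric(cb) / 10), names = names(cb),
                   measure = "betweenness", direction = "higher",
                   class = c("centrality", "numeric"))
  expect_identical(rank_nodes(cb2)$node, rank_nodes(cb)$node)
  expect_equal(spearman_rank(rank_nodes(cb2), rank_nodes(hm))$rho,
               spearman_rank(rank_nodes(cb), rank_nodes(hm))$rho)
  expect_equal(kendall_rank(rank_nodes(cb2), rank_nodes(hm))$tau,
               kendall_rank(rank_nodes(cb), rank_nodes(hm))$tau)
})

test_that("correlation inputs must share a node set", {
  g <- toy_network()
  r1 <- rank_nodes(degree_centrality(g))
  r2 <- rank_nodes(degree_centrality(path_graph(4)))
  expect_error(spearman_rank(r1, r2), "different node sets")
  expect_error(kendall_rank(r1, r2), "different node sets")
  # all pairs tied
  k3 <- complete_graph(3)
  ra <- rank_nodes(degree_centrality(k3), tie_method = "average")
  expect_error(kendall_rank(ra, ra), "undefined")
})

test_that("top-k lists and overlaps follow the id-broken ranks", {
  g <- toy_network()
  cb <- betweenness_centrality(g)
  hm <- heatmap_centrality(g)
  expect_identical(top_nodes(cb, 2), c("6", "8"))
  expect_identical(top_nodes(hm, 2), c("6", "10"))
  expect_equal(topk_overlap(cb, hm, 2), 1L)
  expect_error(top_nodes(cb, 16), "exceeds")
})
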