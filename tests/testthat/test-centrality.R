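test_that("the toy network reproduces the reference centrality table", {
  g <- toy_network()
  ref <- toy_reference()
  tbl <- all_centralities(g)
  expect_identical(tbl$node, ref$node)
  expect_equal(tbl$degree, ref$degree)
  expect_equal(round_half_away(tbl$eigenvector, 3), ref$eigenvector_3dp)
  expect_equal(round_half_away(tbl$closeness, 3), ref$closeness_3dp)
  expect_equal(tbl$betweenness, ref$betweenness)
  expect_equal(round_half_away(tbl$heatmap, 3), ref$heatmap_3dp)
})

test_that("degree centrality counts neighbours", {
  g <- toy_network()
  cd <- degree_centrality(g)
  expect_equal(unname(cd["3"]), 6)
  expect_equal(unname(cd["6"]), 5)
  expect_equal(as.numeric(degree_centrality(path_graph(3))), c(1, 2, 1))
})

test_that("eigenvector centrality is max-normalised, symmetric, and satisfies Ae = lambda e", {
  g <- toy_network()
  ce <- eigenvector_centrality(g)
  expect_equal(max(ce), 1)
  expect_equal(unname(ce["6"]), 0.919, tolerance = 5e-4)
  # nodes 1 and 2 are structurally symmetric leaves of node 3
  expect_equal(unname(ce["1"]), unname(ce["2"]), tolerance = 1e-12)

  # eigen-residual invariant on random connected graphs
  set.seed(3)
  for (i in 1:10) {
    gr <- random_connected_graph(sample(3:50, 1), extra = sample(1:30, 1))
    e <- eigenvector_centrality(gr)
    lam <- attr(e, "lambda_max")
    ax <- vapply(gr$adj, function(nb) sum(e[nb]), numeric(1))
    expect_lt(max(abs(ax - lam * as.numeric(e))), 1e-8)
  }

  expect_error(eigenvector_centrality(graph_from_edges(rbind(c(1, 2), c(3, 4)))),
               "connected")
})

test_that("eigenvector centrality matches a dense eigen-decomposition oracle", {
  set.seed(5)
  for (i in 1:10) {
    g <- random_connected_graph(sample(3:50, 1), extra = sample(0:40, 1))
    A <- matrix(0, g$N, g$N)
    for (v in seq_len(g$N)) A[v, g$adj[[v]]] <- 1
    ed <- eigen(A, symmetric = TRUE)
    ref <- ed$vectors[, which.max(ed$values)]
    ref <- ref / ref[which.max(abs(ref))]
    expect_equal(as.numeric(eigenvector_centrality(g)), ref, tolerance = 1e-8)
  }
})

test_that("power iteration converges on bipartite graphs too", {
  e <- eigenvector_centrality(path_graph(4))
  expect_equal(unname(e[2]), 1)
  expect_equal(unname(e[1]), unname(e[4]), tolerance = 1e-12)
  expect_equal(attr(e, "lambda_max"), 2 * cos(pi / 5), tolerance = 1e-9)
})

test_that("closeness is exactly reciprocal farness", {
  g <- toy_network()
  cc <- closeness_centrality(g)
  expect_equal(unname(cc["6"]), 1 / 28)
  expect_equal(unname(cc["15"]), 1 / 56)
  expect_equal(as.numeric(closeness_centrality(path_graph(2))), c(1, 1))
  expect_equal(as.numeric(cc) * farness(g), rep(1, 15), ignore_attr = TRUE)
  expect_error(closeness_centrality(graph_from_edges(rbind(c(1, 2), c(3, 4)))),
               "disconnected")
})

test_that("Brandes betweenness counts each unordered pair once, endpoints excluded", {
  g <- toy_network()
  cb <- betweenness_centrality(g)
  expect_equal(unname(cb["6"]), 55.5)
  expect_equal(unname(cb["12"]), 13)
  # no shortest path passes through a leaf
  leaves <- names(which(degrees(g) == 1L))
  expect_equal(unname(cb[leaves]), rep(0, length(leaves)))
})

test_that("Brandes matches brute-force shortest-path enumeration on small graphs", {
  set.seed(13)
  for (i in 1:40) {
    g <- random_connected_graph(sample(2:8, 1), extra = sample(0:4, 1))
    expect_equal(as.numeric(betweenness_centrality(g)),
                 unname(brute_betweenness(g)), tolerance = 1e-9)
  }
  # disconnected graphs allowed: unreachable pairs contribute nothing
  disc <- graph_from_edges(rbind(c(1, 2), c(2, 3), c(4, 5)))
  expect_equal(as.numeric(betweenness_centrality(disc)), c(0, 1, 0, 0, 0))
})

test_that("Brandes agrees with igraph on larger random graphs", {
  set.seed(17)
  for (i in 1:10) {
    g <- random_connected_graph(sample(10:40, 1), extra = sample(5:60, 1))
    expect_equal(as.numeric(betweenness_centrality(g)),
                 unname(igraph::betweenness(to_igraph(g))), tolerance = 1e-9)
  }
})

test_that("heatmap centrality equals farness minus mean neighbour farness", {
  g <- toy_network()
  hm <- heatmap_centrality(g)
  expect_equal(unname(hm["6"]), 28 - 176 / 5)
  expect_equal(round_half_away(unname(hm["3"]), 3), -6.667)
  expect_equal(attr(hm, "direction"), "lower")
  # P3: degree {1,2,1}, betweenness {0,1,0}, heatmap {1,-1,1}
  p3 <- path_graph(3)
  expect_equal(as.numeric(heatmap_centrality(p3)), c(1, -1, 1))
  expect_equal(as.numeric(betweenness_centrality(p3)), c(0, 1, 0))

  expect_error(heatmap_centrality(graph_from_edges(rbind(c(1, 2), c(3, 4)))),
               "disconnected")
  # degree-0 error path: single node with no neighbours
  g1 <- preprocess_network(matrix(character(0), ncol = 2), nodes = "a")$graph
  expect_error(heatmap_centrality(g1), "isolated")
})

test_that("every leaf of a connected graph has heatmap value N - 2", {
  g <- toy_network()
  hm <- heatmap_centrality(g)
  leaves <- names(which(degrees(g) == 1L))
  expect_equal(unname(hm[leaves]), rep(13, 6))
  set.seed(19)
  for (i in 1:20) {
    gr <- random_connected_graph(sample(3:15, 1), extra = sample(0:6, 1))
    deg <- degrees(gr)
    if (!any(deg == 1L)) next
    hmr <- heatmap_centrality(gr)
    expect_equal(unname(hmr[names(which(deg == 1L))]),
                 rep(gr$N - 2, sum(deg == 1L)))
  }
})

test_that("degree-weighted heatmap values sum exactly to zero", {
  set.seed(23)
  for (i in 1:20) {
    g <- random_connected_graph(sample(2:20, 1), extra = sample(0:15, 1))
    expect_lt(abs(sum(degrees(g) * as.numeric(heatmap_centrality(g)))), 1e-8)
  }
})

test_that("vertex-transitive graphs score constant under every measure", {
  for (g in list(cycle_graph(6), complete_graph(5))) {
    tbl <- all_centralities(g)
    for (ms in c("degree", "eigenvector", "closeness", "betweenness", "heatmap")) {
      expect_equal(diff(range(tbl[[ms]])), 0, tolerance = 1e-10)
    }
  }
  # K3: all measures identical across nodes
  k3 <- complete_graph(3)
  expect_equal(as.numeric(heatmap_centrality(k3)), rep(0, 3))
})

test_that("shared-sweep table agrees with individual measure calls", {
  g <- toy_network()
  tbl <- all_centralities(g)
  expect_equal(tbl$closeness, as.numeric(closeness_centrality(g)))
  expect_equal(tbl$heatmap, as.numeric(heatmap_centrality(g)))
  vecs <- attr(tbl, "vectors")
  expect_s3_class(vecs$heatmap, "centrality")
  # subset selection works
  sub <- all_centralities(g, c("degree", "heatmap"))
  expect_identical(names(sub), c("node", "degree", "heatmap"))
})
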