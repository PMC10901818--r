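test_that("NWC matches hand values and stays L2-normalized", {
  w <- nwc_iterate(toy_graph("path_3"), 1)$values
  expect_equal(as.numeric(w), c(1, 2, 1) / sqrt(6), tolerance = 1e-12)
  ms <- nwc_iterate(random_connected_graph(20, 0.2, seed = 1), 10)
  expect_true(all(abs(sqrt(colSums(ms$values^2)) - 1) < 1e-12))
  expect_true(all(ms$values >= 0))
})

test_that("NWC order 1 is rank-identical to degree and uniform on regular graphs", {
  g <- random_connected_graph(25, 0.2, seed = 2)
  w1 <- nwc_iterate(g, 1)$values[, 1]
  expect_equal(kendall_tau(w1, igraph::degree(g)), 1.0)
  ws <- nwc_iterate(toy_graph("cycle_8"), 5)$values
  expect_true(all(abs(ws - 1 / sqrt(8)) < 1e-12))
})

test_that("NWC at large K recovers eigenvector centrality rank order", {
  g <- random_connected_graph(15, 0.25, seed = 4)  # gnp; almost surely non-bipartite
  w30 <- nwc_iterate(g, 30)$values[, 30]
  ev <- eigen(dense_adj(g), symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)
  expect_equal(kendall_tau(w30, ev), 1.0)
  expect_error(nwc_iterate(igraph::make_empty_graph(3, directed = FALSE), 2),
               "without edges")
})

test_that("VP matches the hand-evaluated update and conserves probability", {
  p <- vp_iterate(toy_graph("path_3"), 1)$values
  expect_equal(as.numeric(p), c(0.19166667, 0.61666667, 0.19166667),
               tolerance = 1e-8)
  ms <- vp_iterate(random_connected_graph(20, 0.2, seed = 5), 10)
  expect_true(all(abs(colSums(ms$values) - 1) < 1e-12))
  expect_true(all(ms$values > 0 & ms$values < 1))
})

test_that("VP is uniform on regular graphs and converges to the PageRank fixed point", {
  pr <- vp_iterate(toy_graph("cycle_6"), 4)$values
  expect_true(all(abs(pr - 1 / 6) < 1e-14))
  g <- random_connected_graph(18, 0.2, seed = 6)
  p100 <- vp_iterate(g, 100)$values[, 100]
  # oracle: direct linear solve (I - alpha A^T D^-1) p = (1-alpha)/N u
  A <- dense_adj(g)
  d <- rowSums(A)
  n <- nrow(A)
  pstar <- solve(diag(n) - 0.85 * t(A) %*% diag(1 / d), rep(0.15 / n, n))
  expect_lt(sum(abs(p100 - pstar)), 1e-8)
  expect_error(vp_iterate(g, 2, alpha = 1.2), "alpha")
  expect_error(vp_iterate(igraph::disjoint_union(g, igraph::make_empty_graph(1, directed = FALSE)), 2),
               "isolated")
})

test_that("HI starts at degree, decreases monotonically, and fixes at coreness", {
  h <- hi_iterate(toy_graph("star_5"), 2)$values
  expect_equal(h[, 1], c(4L, 1L, 1L, 1L, 1L))
  expect_equal(h[, 2], rep(1L, 5))
  hr <- hi_iterate(toy_graph("cycle_7"), 6)$values
  expect_true(all(hr == 2L))
  for (s in 1:4) {
    g <- random_connected_graph(30, 0.12, seed = s)
    H <- hi_iterate(g, 12)$values
    expect_equal(H[, 1], as.integer(igraph::degree(g)))
    expect_true(all(H[, -1] - H[, -ncol(H)] <= 0))  # non-increasing per node
    fp <- hi_fixed_point(g)
    expect_equal(fp$values, oracle_coreness(g))
    expect_equal(fp$values, as.integer(igraph::coreness(g)))
    expect_true(all(H >= matrix(fp$values, 30, 12)))
  }
})

test_that("benchmark centralities match by-hand values on small graphs", {
  b <- benchmark_centralities(toy_graph("path_3"))
  expect_equal(b$degree, c(1, 2, 1))
  expect_equal(b$neighborhood, c(2, 2, 2))
  expect_equal(b$twohop, c(1, 0, 1))  # endpoints see the far endpoint
  k4 <- benchmark_centralities(toy_graph("complete_4"))
  expect_equal(k4$closeness, rep(1, 4))
  expect_equal(k4$coreness, rep(3, 4))
  expect_error(benchmark_centralities(toy_graph("two_triangles")), "connected")
})

test_that("converged eigenvector/PageRank agree with igraph", {
  g <- random_connected_graph(25, 0.15, seed = 8)
  ev <- eigenvector_converged(g)
  ig <- igraph::eigen_centrality(g)$vector
  expect_equal(kendall_tau(ev, ig), 1.0)
  pr <- pagerank_converged(g)
  ig_pr <- igraph::page_rank(g, damping = 0.85)$vector
  expect_lt(max(abs(pr - ig_pr)), 1e-6)
})

test_that("convergence profiles hit tau = 1 at the fixed point", {
  g <- random_connected_graph(20, 0.2, seed = 10)
  ms <- nwc_iterate(g, 8)
  prof <- convergence_profile(ms, ms$values[, 8])
  expect_equal(prof$tau[8], 1.0)
  fp <- hi_fixed_point(g)
  hprof <- convergence_profile(hi_iterate(g, fp$iterations + 1L),
                               as.numeric(fp$values))
  expect_equal(hprof$tau[fp$iterations + 1L], 1.0)
  expect_error(convergence_profile(ms, 1:5), "length")
})

test_that("one iteration costs O(|E|): runtime scales linearly in edges", {
  # property check at coarse granularity: doubling edges roughly doubles
  # work, far from quadratic
  g1 <- igraph::sample_gnm(2000, 8000)
  g2 <- igraph::sample_gnm(2000, 32000)
  t1 <- system.time(nwc_iterate(g1, 20))[["elapsed"]]
  t2 <- system.time(nwc_iterate(g2, 20))[["elapsed"]]
  expect_lt(t2, max(t1, 0.02) * 16)  # 4x edges must stay well below 16x time
})
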