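test_that("edge list reading simplifies directions, self-loops and duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("a b", "b a", "b b", "b c"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::gsize(g), 2L)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(unname(sort(igraph::degree(g))), c(1, 1, 2))
})

test_that("KONECT-style comment headers and extra columns are handled", {
  f <- withr::local_tempfile()
  writeLines(c("% sym unweighted", "% another comment", "1 2 1 1020304050"), f)
  g <- read_edge_list(f, dialect = "konect")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::gsize(g), 1L)
  # plain dialect rejects the extra columns, reporting the line number
  expect_error(read_edge_list(f, dialect = "plain"), "line 3")
})

test_that("reading errors: malformed lines and empty edge sets", {
  f <- withr::local_tempfile()
  writeLines(c("a b", "c"), f)
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile()
  writeLines(c("% only comments"), f2)
  expect_error(read_edge_list(f2), "empty edge set")
  f3 <- withr::local_tempfile()
  writeLines(c("a a"), f3)
  expect_error(read_edge_list(f3), "empty edge set")
})

test_that("a large random edge file reloads consistently with an independent parse", {
  f <- withr::local_tempfile()
  set.seed(42)
  from <- sample(letters, 1000, replace = TRUE)
  to <- sample(LETTERS, 1000, replace = TRUE)
  writeLines(paste(from, to), f)
  g <- read_edge_list(f)
  # independent line-by-line recount
  seen <- unique(c(from, to))
  keys <- unique(paste(pmin(from, to), pmax(from, to)))
  keys <- keys[vapply(strsplit(keys, " "), function(x) x[1] != x[2], logical(1))]
  expect_equal(igraph::vcount(g), length(seen))
  expect_equal(igraph::gsize(g), length(keys))
  expect_equal(sum(igraph::degree(g)), 2L * igraph::gsize(g))
})

test_that("largest_component keeps the biggest piece and is identity on connected input", {
  p3 <- toy_graph("path_3")
  expect_equal(igraph::vcount(largest_component(p3)), 3L)
  gi <- igraph::disjoint_union(p3, igraph::make_empty_graph(1, directed = FALSE))
  expect_equal(igraph::vcount(largest_component(gi)), 3L)
  g2 <- igraph::disjoint_union(toy_graph("cycle_5"), toy_graph("path_3"))
  lcc <- largest_component(g2)
  expect_equal(igraph::vcount(lcc), 5L)
  expect_true(igraph::is_connected(lcc))
  # oracle: component labelling via igraph BFS from every node
  comp_sizes <- table(igraph::components(g2)$membership)
  expect_equal(igraph::vcount(lcc), max(comp_sizes))
})

test_that("diameter matches known values and the Floyd-Warshall oracle", {
  expect_equal(graph_diameter(toy_graph("path_3")), 2L)
  expect_equal(graph_diameter(toy_graph("cycle_6")), 3L)
  expect_equal(graph_diameter(toy_graph("complete_5")), 1L)
  expect_error(graph_diameter(toy_graph("two_triangles")), "disconnected")
  for (s in 1:5) {
    g <- random_connected_graph(30, 0.1, seed = s)
    expect_equal(graph_diameter(g), oracle_diameter(g))
  }
})

test_that("modularity matches hand values, the all-singletons identity and igraph", {
  tt <- toy_graph("two_triangles")
  expect_equal(modularity_q(tt, rep(1, 6)), 0)
  expect_equal(modularity_q(tt, igraph::V(tt)$community), 0.5)
  g <- random_connected_graph(25, 0.2, seed = 3)
  d <- igraph::degree(g)
  m <- igraph::gsize(g)
  expect_equal(modularity_q(g, seq_len(25)), -sum((d / (2 * m))^2))
  part <- sample(1:3, 25, replace = TRUE)
  expect_equal(modularity_q(g, part), igraph::modularity(g, part))
  expect_error(modularity_q(igraph::make_empty_graph(3, directed = FALSE), 1:3),
               "without edges")
})

test_that("k-hop coverage: hand values, monotonicity, saturation at the diameter", {
  expect_equal(khop_coverage(toy_graph("complete_5"), 1), 1.0)
  expect_equal(khop_coverage(toy_graph("path_3"), 1), 7 / 9)
  g <- random_connected_graph(40, 0.08, seed = 9)
  dia <- graph_diameter(g)
  cov <- vapply(seq_len(dia), function(k) khop_coverage(g, k), numeric(1))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[dia], 1.0)
  if (dia > 1) expect_lt(cov[1], 1.0)
  expect_error(khop_coverage(g, 0), "k must be")
})

test_that("graph summary reports the basic descriptors", {
  s <- graph_summary(toy_graph("cycle_6"))
  expect_equal(s$n, 6L)
  expect_equal(s$m, 6L)
  expect_equal(s$mean_degree, 2)
  expect_equal(s$diameter, 3L)
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_summary(toy_graph("cycle_6"), f)
  expect_equal(jsonlite::read_json(f)$diameter, 3L)
})
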