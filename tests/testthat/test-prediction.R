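test_that("split sizes, disjointness and determinism", {
  set.seed(1)
  sp <- split_nodes(100, 0.1)
  expect_length(sp$train, 10L)
  expect_length(sp$test, 90L)
  expect_length(intersect(sp$train, sp$test), 0L)
  set.seed(99)
  a <- split_nodes(60, 0.2)
  set.seed(99)
  b <- split_nodes(60, 0.2)
  expect_identical(a, b)
  expect_error(split_nodes(10, 0.1), "too small")
})

test_that("each node is included in the training set at the nominal frequency", {
  n <- 50
  q <- 0.1
  reps <- 2000
  set.seed(2)
  counts <- integer(n)
  for (r in seq_len(reps)) {
    counts[split_nodes(n, q)$train] <- counts[split_nodes(n, q)$train] + 1L
  }
  freq <- counts / reps
  # binomial 4-sigma band around q
  band <- 4 * sqrt(q * (1 - q) / reps)
  expect_true(all(abs(freq - q) < band))
})

test_that("random forest recovers a smooth function of the features", {
  set.seed(3)
  n <- 300
  x <- cbind(a = runif(n), b = runif(n))
  y <- x[, 1]  # target equals one feature exactly
  sp <- split_nodes(n, 0.3)
  yhat <- fit_and_predict(x, y, sp$train, sp$test, seed = 4)
  expect_gt(r_squared(y[sp$test], yhat), 0.9)
})

test_that("permuted feature-target pairing carries no signal", {
  set.seed(5)
  n <- 200
  x <- matrix(runif(n * 3), n, 3)
  y <- x[, 1] + 0.1 * rnorm(n)
  r2 <- vapply(1:5, function(s) {
    set.seed(s)
    yp <- sample(y)
    sp <- split_nodes(n, 0.3)
    yhat <- fit_and_predict(x, yp, sp$train, sp$test, seed = s)
    r_squared(yp[sp$test], yhat)
  }, numeric(1))
  expect_lt(mean(r2), 0.15)
})

test_that("ridge recovers an exactly linear target up to regularization bias", {
  set.seed(6)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4)
  y <- drop(x %*% c(2, -1, 0.5, 3)) + 7
  sp <- split_nodes(n, 0.5)
  yhat <- fit_and_predict(x, y, sp$train, sp$test, regressor = "ridge")
  expect_gt(r_squared(y[sp$test], yhat), 0.999)
})

test_that("a constant training target warns and predicts the constant", {
  x <- matrix(runif(40), 20, 2)
  y <- c(rep(5, 10), runif(10))
  expect_warning(
    pred <- fit_and_predict(x, y, train = 1:10, test = 11:20),
    "constant"
  )
  expect_equal(pred, rep(5, 10))
})

test_that("r_squared matches hand values and its defining identities", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("kendall_tau matches hand values, cor() and a brute-force counter", {
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 2)), 0.5)
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "entirely tied")
  set.seed(7)
  for (r in 1:5) {
    a <- sample(1:20, 200, replace = TRUE)  # heavy ties
    b <- a + sample(-3:3, 200, replace = TRUE)
    expect_equal(kendall_tau(a, b), oracle_tau(a, b), tolerance = 1e-12)
    expect_equal(kendall_tau(a, b),
                 stats::cor(a, b, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("recognition rate counts the overlap of equal-length top lists", {
  s <- 20:1
  expect_equal(recognition_rate(s, s), 1.0)
  s_hat2 <- s
  s_hat2[1] <- 0  # drop true best out of predicted top-2
  expect_equal(recognition_rate(s_hat2, s, f_percent = 10), 0.5)
  expect_equal(recognition_rate(-s + 42, s, f_percent = 10), 0.0)
  # ceiling list size: 7 test nodes at f = 10% still compares top-1 lists
  expect_equal(recognition_rate(7:1, 7:1, f_percent = 10), 1.0)
})

test_that("rank measures are invariant to strictly increasing transforms", {
  set.seed(8)
  a <- runif(50)
  b <- runif(50)
  expect_equal(kendall_tau(a, b), kendall_tau(exp(3 * a), b^3 + b))
  expect_equal(recognition_rate(a, b, 10), recognition_rate(log(a + 1), b, 10))
})

test_that("run_experiment aggregates realizations correctly and reproducibly", {
  set.seed(9)
  n <- 120
  x <- cbind(f = runif(n))
  y <- x[, 1] + 0.05 * rnorm(n)
  cfg1 <- experiment_config(q = 0.3, realizations = 1L, K = 1L, rng_seed = 10)
  cfg5 <- experiment_config(q = 0.3, realizations = 5L, K = 1L, rng_seed = 10)
  r1 <- run_experiment(x, y, cfg1)
  r5 <- run_experiment(x, y, cfg5)
  expect_equal(nrow(r1), 1L)
  expect_equal(summary(r1)$mean[1], r1$r_squared[1])
  expect_equal(summary(r5)$mean,
               colMeans(r5[, c("r_squared", "kendall_tau", "recognition_rate")]),
               ignore_attr = TRUE)
  # realization 1 of the 5-realization run equals the single-realization run
  expect_equal(as.data.frame(r5)[1, ], as.data.frame(r1)[1, ], ignore_attr = TRUE)
  r5b <- run_experiment(x, y, cfg5)
  expect_equal(as.data.frame(r5), as.data.frame(r5b))
})

test_that("full pipeline recovers a noisy monotone function of degree", {
  g <- random_connected_graph(200, 0.1, seed = 11)
  deg <- igraph::degree(g)
  set.seed(12)
  signal <- deg^1.5
  y <- signal + 0.1 * stats::sd(signal) * rnorm(length(deg))
  ms <- nwc_iterate(g, 4)
  rep <- run_experiment(ms, y, experiment_config(q = 0.3, realizations = 10L,
                                                 K = 4L, rng_seed = 13))
  expect_gt(summary(rep)$mean[2], 0.8)  # kendall_tau
})
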