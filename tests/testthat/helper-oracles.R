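# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense linear algebra, peeling, brute-force pair
# counting, exact CTMC enumeration, and a direct Gillespie simulator.

dense_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# A^k u / ||A^k u||_2 via dense matrix powers
oracle_nwc <- function(g, K) {
  A <- dense_adj(g)
  n <- nrow(A)
  out <- matrix(0, n, K)
  v <- rep(1, n) / sqrt(n)
  for (k in seq_len(K)) {
    v <- A %*% v
    v <- v / sqrt(sum(v^2))
    out[, k] <- v
  }
  out
}

# Google-matrix powers: G = alpha * A^T D^-1 + (1-alpha)/n * u u^T
oracle_vp <- function(g, K, alpha = 0.85) {
  A <- dense_adj(g)
  n <- nrow(A)
  d <- rowSums(A)
  G <- alpha * t(A) %*% diag(1 / d, n) + (1 - alpha) / n * matrix(1, n, n)
  out <- matrix(0, n, K)
  p <- rep(1 / n, n)
  for (k in seq_len(K)) {
    p <- G %*% p
    out[, k] <- p
  }
  out
}

# k-core coreness by repeated peeling
oracle_coreness <- function(g) {
  A <- dense_adj(g)
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- which(deg <= k)
      if (!length(low)) break
      idx <- which(alive)[low]
      core[idx] <- k
      alive[idx] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
  }
  core
}

# Kendall tau-b by explicit double loop
oracle_tau <- function(a, b) {
  n <- length(a)
  nc <- nd <- ta <- tb <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      da <- a[i] - a[j]
      db <- b[i] - b[j]
      if (da == 0 && db == 0) next
      if (da == 0) ta <- ta + 1
      else if (db == 0) tb <- tb + 1
      else if (da * db > 0) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  (nc - nd) / sqrt((nc + nd + tb) * (nc + nd + ta))
}

# Exact expected outbreak size of the continuous-time Markov SIR process on
# a tiny graph, by memoized enumeration over the 3^n state space (S=0, I=1,
# R=2). The embedded jump chain is acyclic because states only progress.
oracle_ctmc_outbreak <- function(g, seed_node, beta, gamma = 1) {
  A <- dense_adj(g)
  n <- nrow(A)
  memo <- new.env(hash = TRUE)
  expect_size <- function(state) {
    key <- paste(state, collapse = "")
    if (!is.null(memo[[key]])) return(memo[[key]])
    inf <- which(state == 1L)
    if (!length(inf)) {
      val <- sum(state == 2L)
    } else {
      rates <- numeric(0)
      nexts <- list()
      for (i in inf) {
        s2 <- state; s2[i] <- 2L
        rates <- c(rates, gamma); nexts <- c(nexts, list(s2))
      }
      for (u in which(state == 0L)) {
        ninf <- sum(A[u, inf])
        if (ninf > 0) {
          s2 <- state; s2[u] <- 1L
          rates <- c(rates, beta * ninf); nexts <- c(nexts, list(s2))
        }
      }
      total <- sum(rates)
      val <- sum(vapply(seq_along(rates), function(j)
        rates[j] / total * expect_size(nexts[[j]]), numeric(1)))
    }
    memo[[key]] <- val
    val
  }
  s0 <- rep(0L, n)
  s0[seed_node] <- 1L
  expect_size(s0)
}

# Direct (Gillespie) SIR simulator in plain R: at each step, sample among
# all recovery and infection events proportionally to their rates.
oracle_gillespie_sir <- function(g, seed_node, beta, gamma = 1) {
  A <- dense_adj(g)
  n <- nrow(A)
  state <- rep(0L, n)
  state[seed_node] <- 1L
  repeat {
    inf <- which(state == 1L)
    if (!length(inf)) break
    sus <- which(state == 0L)
    inf_rates <- if (length(sus)) beta * rowSums(A[sus, inf, drop = FALSE]) else numeric(0)
    rates <- c(rep(gamma, length(inf)), inf_rates)
    targets <- c(inf, sus)
    active <- rates > 0
    pick <- sample(length(rates), 1L, prob = rates)
    if (pick <= length(inf)) state[targets[pick]] <- 2L else state[targets[pick]] <- 1L
  }
  sum(state == 2L)
}

# All-pairs shortest paths by Floyd-Warshall
oracle_diameter <- function(g) {
  A <- dense_adj(g)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  max(D)
}

random_connected_graph <- function(n, p = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::gsize(g) > 0) return(g)
  }
}
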