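# Continuous-time SIR spreading: nodal influence estimation and
# epidemic-threshold estimation via variability maximization.

#' SIR simulation configuration
#'
#' @param beta Infection rate per infected neighbor (> 0).
#' @param gamma Recovery rate (> 0, default 1, so the effective infection
#'   rate is `lambda = beta / gamma = beta`).
#' @param runs Realizations per seed node (default 1e4).
#' @param seed Integer root seed; per-(node, run) RNG substreams are derived
#'   from it, so results are invariant to execution order.
#' @return An object of class `sir_config`.
#' @export
sir_config <- function(beta, gamma = 1, runs = 1e4, seed = 1L) {
  stopifnot(beta > 0, gamma > 0, runs >= 1)
  structure(list(beta = beta, gamma = gamma, runs = as.integer(runs),
                 seed = seed),
            class = "sir_config")
}

# CSR adjacency (0-based) for the C++ simulator.
.graph_csr <- function(g) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  list(ptr = c(0L, cumsum(lengths(adj))),
       idx = if (length(adj)) unlist(adj, use.names = FALSE) - 1L else integer(0))
}

.resolve_nodes <- function(g, nodes) {
  if (is.character(nodes)) {
    out <- match(nodes, igraph::V(g)$name)
    if (anyNA(out)) stop("unknown node label(s): ",
                         paste(nodes[is.na(out)], collapse = ", "))
    out
  } else {
    out <- as.integer(nodes)
    if (any(out < 1L | out > igraph::vcount(g))) stop("node index out of range")
    out
  }
}

#' Simulate one SIR outbreak
#'
#' Runs a single exact realization of the continuous-time Markov SIR
#' process seeded at one node and returns the final outbreak size (number
#' of ever-infected nodes, seed included).
#'
#' @param g An undirected graph.
#' @param seed_node Node index or label.
#' @param config An [sir_config()].
#' @param run Which RNG substream to use (default 0); successive values
#'   give independent realizations.
#' @return Integer outbreak size in `[1, N]`.
#' @export
simulate_sir <- function(g, seed_node, config, run = 0L) {
  stopifnot(inherits(config, "sir_config"))
  v <- .resolve_nodes(g, seed_node)
  stopifnot(length(v) == 1L)
  csr <- .graph_csr(g)
  sizes <- sir_outbreaks_cpp(csr$ptr, csr$idx, v - 1L, 1L,
                             config$beta, config$gamma,
                             as.numeric(.derive_seed(config$seed, run)))
  as.integer(sizes[1L])
}

#' Raw outbreak sizes for one seed node
#'
#' @inheritParams simulate_sir
#' @param runs Number of realizations (overrides `config$runs` if given).
#' @return Integer vector of outbreak sizes.
#' @export
sir_outbreak_sizes <- function(g, seed_node, config, runs = config$runs) {
  stopifnot(inherits(config, "sir_config"))
  v <- .resolve_nodes(g, seed_node)
  stopifnot(length(v) == 1L)
  csr <- .graph_csr(g)
  as.integer(sir_outbreaks_cpp(csr$ptr, csr$idx, v - 1L, as.integer(runs),
                               config$beta, config$gamma,
                               as.numeric(config$seed)))
}

#' Estimate nodal spreading influence
#'
#' The spreading influence of a node is the mean final outbreak size over
#' `config$runs` independent SIR realizations seeded at the node.
#'
#' @param g An undirected graph.
#' @param nodes Node indices or labels (default: all nodes).
#' @param config An [sir_config()].
#' @return An `influence_table` data frame with columns `node`,
#'   `influence`, `stderr`, `runs` and attribute `lambda` (= beta/gamma).
#' @export
estimate_influence <- function(g, nodes = NULL, config = sir_config(beta = 1)) {
  stopifnot(inherits(config, "sir_config"))
  n <- igraph::vcount(g)
  v <- if (is.null(nodes)) seq_len(n) else .resolve_nodes(g, nodes)
  if (!length(v)) stop("nodes must be non-empty")
  csr <- .graph_csr(g)
  res <- sir_influence_cpp(csr$ptr, csr$idx, v - 1L, config$runs,
                           config$beta, config$gamma, as.numeric(config$seed))
  labels <- igraph::V(g)$name
  out <- data.frame(
    node = if (is.null(labels)) v else labels[v],
    influence = res[, 1L],
    stderr = res[, 2L] / sqrt(config$runs),
    runs = config$runs,
    stringsAsFactors = FALSE
  )
  attr(out, "lambda") <- config$beta / config$gamma
  attr(out, "node_index") <- v
  class(out) <- c("influence_table", "data.frame")
  out
}

#' Variability (coefficient of variation) of nodal influence
#'
#' \eqn{\sqrt{\langle\rho^2\rangle - \langle\rho\rangle^2} /
#' \langle\rho\rangle}, where \eqn{\rho} is the influence of a node drawn
#' uniformly from the table. The epidemic threshold is estimated as the
#' effective infection rate maximizing this quantity.
#'
#' @param x An `influence_table` or a numeric vector of influences.
#' @return A non-negative real number.
#' @export
variability <- function(x) {
  vals <- if (inherits(x, "influence_table")) x$influence else as.numeric(x)
  if (length(vals) < 2L) stop("variability requires at least two nodes")
  m1 <- mean(vals)
  if (m1 <= 0) stop("mean influence must be positive")
  m2 <- mean(vals^2)
  sqrt(max(m2 - m1^2, 0)) / m1
}

#' Estimate the epidemic threshold by variability maximization
#'
#' Scans a grid of effective infection rates, estimates nodal influence for
#' a node sample at each rate, and returns the rate maximizing the
#' variability of influence across nodes. Ties are broken toward the
#' smaller rate.
#'
#' @param g An undirected connected graph.
#' @param lambda_grid Ascending grid of effective infection rates (>= 3
#'   points). Default: 20 linearly spaced points spanning 0.1 to 3 times
#'   the mean-field estimate \eqn{\langle d\rangle / (\langle d^2\rangle -
#'   \langle d\rangle)}.
#' @param config An [sir_config()]; its `beta` is ignored (the grid is
#'   used), `gamma`, `runs` and `seed` are honored.
#' @param sample_size Number of seed nodes used per grid point. Default:
#'   all nodes when `N <= 2000`, else a seeded uniform sample of 2000.
#' @return A `threshold_scan` list with `lambda_grid`, `variability`,
#'   `lambda_c`, `sample_size`, `runs`.
#' @export
estimate_threshold <- function(g, lambda_grid = NULL,
                               config = sir_config(beta = 1, runs = 1000),
                               sample_size = NULL) {
  stopifnot(inherits(config, "sir_config"))
  n <- igraph::vcount(g)
  if (is.null(lambda_grid)) {
    d <- igraph::degree(g)
    lc0 <- mean(d) / (mean(d^2) - mean(d))
    lambda_grid <- seq(0.1, 3, length.out = 20) * lc0
  }
  if (length(lambda_grid) < 3L || any(diff(lambda_grid) <= 0)) {
    stop("lambda_grid must be an ascending grid with at least 3 points")
  }
  if (is.null(sample_size)) sample_size <- if (n <= 2000L) n else 2000L
  if (sample_size < 2L) stop("sample_size must be >= 2")
  nodes <- if (sample_size >= n) seq_len(n) else {
    .seeded_sample(.derive_seed(config$seed, 9901L), n, sample_size)
  }
  vari <- vapply(seq_along(lambda_grid), function(l) {
    cfg <- sir_config(beta = lambda_grid[l] * config$gamma,
                      gamma = config$gamma, runs = config$runs,
                      seed = .derive_seed(config$seed, l))
    variability(estimate_influence(g, nodes, cfg))
  }, numeric(1L))
  structure(list(lambda_grid = lambda_grid, variability = vari,
                 lambda_c = lambda_grid[which.max(vari)],
                 sample_size = length(nodes), runs = config$runs),
            class = "threshold_scan")
}

# Seeded uniform sample without disturbing the caller's RNG stream.
.seeded_sample <- function(seed, n, size) {
  state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  sort(sample.int(n, size))
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %d grid points in [%.4g, %.4g], lambda_c = %.4g\n",
              length(x$lambda_grid), min(x$lambda_grid), max(x$lambda_grid),
              x$lambda_c))
  invisible(x)
}

#' @export
as.data.frame.threshold_scan <- function(x, ...) {
  data.frame(lambda = x$lambda_grid, variability = x$variability)
}
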