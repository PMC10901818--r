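# Iterative metric sets: normalized walk counts (NWC), visiting
# probabilities (VP) and iterative H-indices (HI). Each order-k column uses
# only information within k hops of a node (k+1 hops for VP, whose update
# consumes neighbor degrees) and converges, as k grows, to a classical
# global centrality: eigenvector centrality, PageRank and coreness.

.adjacency <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = TRUE)
}

new_metric_set <- function(metric, values, alpha = NULL) {
  colnames(values) <- paste0("order_", seq_len(ncol(values)))
  structure(list(metric = metric, values = values, K = ncol(values),
                 alpha = alpha),
            class = "iterative_metric_set")
}

#' @export
print.iterative_metric_set <- function(x, ...) {
  cat(sprintf("<iterative_metric_set> %s: %d nodes, orders 1..%d\n",
              toupper(x$metric), nrow(x$values), x$K))
  invisible(x)
}

#' Normalized walk counts (NWC)
#'
#' Truncated power iteration for eigenvector centrality. Starting from the
#' L2-normalized all-one vector \eqn{w^{(0)} = u/\sqrt{N}}, each order is
#' \eqn{w^{(k)} = A w^{(k-1)} / \lVert A w^{(k-1)} \rVert_2}, i.e. the
#' normalized count of distinct k-hop walks leaving each node. As
#' \eqn{k \to \infty}, \eqn{w^{(k)}} converges to the eigenvector
#' centrality.
#'
#' @param g An undirected graph with at least one edge.
#' @param K Maximum order, integer >= 1.
#' @return An `iterative_metric_set` whose `values` matrix has one column
#'   per order; every column has unit Euclidean norm and non-negative
#'   entries.
#' @export
nwc_iterate <- function(g, K) {
  stopifnot(K >= 1)
  if (igraph::gsize(g) == 0L) stop("NWC is undefined on a graph without edges")
  A <- .adjacency(g)
  n <- nrow(A)
  W <- matrix(0, n, K)
  w <- rep(1 / sqrt(n), n)
  for (k in seq_len(K)) {
    v <- as.numeric(A %*% w)
    nrm <- sqrt(sum(v * v))
    if (nrm == 0) stop("NWC iteration collapsed to zero (no edges)")
    w <- v / nrm
    W[, k] <- w
  }
  rownames(W) <- igraph::V(g)$name
  new_metric_set("nwc", W)
}

#' Visiting probabilities (VP)
#'
#' Truncated PageRank iteration. Starting from the uniform distribution
#' \eqn{p^{(0)} = u/N}, each order applies
#' \eqn{p_i^{(k)} = \alpha \sum_j A_{ji} p_j^{(k-1)}/d_j + (1-\alpha)/N}:
#' the probability that a teleporting random walker occupies node i after k
#' steps. Converges to PageRank as k grows. Note the order-k value uses
#' (k+1)-hop information, since the update consumes neighbor degrees.
#'
#' @param g An undirected graph without isolated nodes (restrict to the
#'   largest component first).
#' @param K Maximum order, integer >= 1.
#' @param alpha Teleportation parameter in (0, 1); default 0.85.
#' @return An `iterative_metric_set`; every column sums to 1.
#' @export
vp_iterate <- function(g, K, alpha = 0.85) {
  stopifnot(K >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  d <- igraph::degree(g)
  if (any(d == 0)) {
    stop("VP requires no isolated nodes; restrict to the largest component")
  }
  A <- .adjacency(g)
  n <- nrow(A)
  P <- matrix(0, n, K)
  p <- rep(1 / n, n)
  for (k in seq_len(K)) {
    p <- as.numeric(alpha * (A %*% (p / d)) + (1 - alpha) / n)
    P[, k] <- p
  }
  rownames(P) <- igraph::V(g)$name
  new_metric_set("vp", P, alpha = alpha)
}

# Hirsch operator: largest integer x such that at least x of the values
# are >= x. H[] of an empty vector is 0 (degree-0 node).
.hirsch <- function(vals) {
  if (!length(vals)) return(0L)
  s <- sort(vals, decreasing = TRUE)
  sum(s >= seq_along(s))
}

#' Iterative H-indices (HI)
#'
#' The order-1 value is the degree, \eqn{h^{(1)}_i = d_i}; order k applies
#' the Hirsch operator to the neighbors' order-(k-1) values:
#' \eqn{h^{(k)}_i} is the largest integer x such that at least x neighbors
#' j have \eqn{h^{(k-1)}_j \ge x}. Per-node values are non-increasing in k
#' and reach the node's coreness in finitely many iterations.
#'
#' @param g An undirected graph.
#' @param K Maximum order, integer >= 1.
#' @return An `iterative_metric_set` with integer-valued columns.
#' @export
hi_iterate <- function(g, K) {
  stopifnot(K >= 1)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  n <- length(adj)
  H <- matrix(0L, n, K)
  h <- as.integer(igraph::degree(g))
  H[, 1L] <- h
  if (K > 1L) {
    for (k in 2:K) {
      h <- vapply(adj, function(nb) .hirsch(h[nb]), integer(1L))
      H[, k] <- h
    }
  }
  rownames(H) <- igraph::V(g)$name
  new_metric_set("hi", H)
}

#' H-index fixed point (coreness)
#'
#' Iterates the Hirsch update until it stops changing; the fixed point is
#' the k-core coreness of every node.
#'
#' @param g An undirected graph.
#' @param max_iter Safety cap on iterations (default: number of nodes + 1).
#' @return A list with `values` (integer coreness per node) and
#'   `iterations` (first order at which the fixed point is reached).
#' @export
hi_fixed_point <- function(g, max_iter = igraph::vcount(g) + 1L) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  h <- as.integer(igraph::degree(g))
  for (k in seq_len(max_iter)) {
    h_new <- vapply(adj, function(nb) .hirsch(h[nb]), integer(1L))
    if (identical(h_new, h)) {
      return(list(values = h, iterations = k))
    }
    h <- h_new
  }
  stop("H-index iteration did not reach a fixed point within max_iter")
}

#' Converged eigenvector centrality by power iteration
#'
#' Power iteration continued until successive iterates differ by less than
#' `tol` in L1 norm (or `max_iter` is hit).
#'
#' @param g An undirected connected graph with at least one edge.
#' @param tol L1 stopping tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return Numeric vector of unit L2 norm.
#' @export
eigenvector_converged <- function(g, tol = 1e-10, max_iter = 1000L) {
  A <- .adjacency(g)
  n <- nrow(A)
  w <- rep(1 / sqrt(n), n)
  for (k in seq_len(max_iter)) {
    v <- as.numeric(A %*% w)
    nrm <- sqrt(sum(v * v))
    if (nrm == 0) stop("power iteration collapsed to zero")
    v <- v / nrm
    if (sum(abs(v - w)) < tol) return(v)
    w <- v
  }
  w
}

#' Converged PageRank by fixed-point iteration
#'
#' @inheritParams vp_iterate
#' @param tol L1 stopping tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return Numeric probability vector (sums to 1).
#' @export
pagerank_converged <- function(g, alpha = 0.85, tol = 1e-10, max_iter = 1000L) {
  d <- igraph::degree(g)
  if (any(d == 0)) stop("PageRank requires no isolated nodes")
  A <- .adjacency(g)
  n <- nrow(A)
  p <- rep(1 / n, n)
  for (k in seq_len(max_iter)) {
    p_new <- as.numeric(alpha * (A %*% (p / d)) + (1 - alpha) / n)
    if (sum(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  p
}

#' The seven-centrality benchmark feature set
#'
#' Classic local and global centralities used as the benchmark regression
#' features: degree; neighborhood (sum of degrees of direct neighbors);
#' two-hop neighborhood (sum of degrees of nodes exactly two hops away);
#' coreness; eigenvector centrality; PageRank (alpha = 0.85); and closeness
#' \eqn{(N-1)/\sum_j dist(i,j)}.
#'
#' @param g A connected undirected graph.
#' @param alpha Teleportation parameter for PageRank.
#' @return A data frame with a `node` column followed by the seven metrics.
#' @export
benchmark_centralities <- function(g, alpha = 0.85) {
  if (!igraph::is_connected(g)) {
    stop("benchmark centralities require a connected graph")
  }
  d <- igraph::degree(g)
  A <- .adjacency(g)
  two <- igraph::ego(g, order = 2, mindist = 2)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_along(d))
  data.frame(
    node = nodes,
    degree = as.numeric(d),
    neighborhood = as.numeric(A %*% d),
    twohop = vapply(two, function(v) sum(d[as.integer(v)]), numeric(1L)),
    coreness = as.numeric(igraph::coreness(g)),
    eigenvector = eigenvector_converged(g),
    pagerank = pagerank_converged(g, alpha = alpha),
    closeness = as.numeric(igraph::closeness(g, normalized = TRUE)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Convergence profile of an iterative metric set
#'
#' Kendall's tau-b between each order of an iterative metric set and a
#' target centrality vector (typically the converged global metric).
#'
#' @param ms An `iterative_metric_set`.
#' @param target Numeric vector, one value per node.
#' @return A data frame with columns `order` and `tau`.
#' @export
convergence_profile <- function(ms, target) {
  stopifnot(inherits(ms, "iterative_metric_set"))
  if (length(target) != nrow(ms$values)) {
    stop("target length must match the number of nodes in the metric set")
  }
  tau <- vapply(seq_len(ms$K),
                function(k) kendall_tau(ms$values[, k], target),
                numeric(1L))
  data.frame(order = seq_len(ms$K), tau = tau)
}
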