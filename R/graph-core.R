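#' Read an undirected simple graph from a whitespace edge list
#'
#' Reads a two-column whitespace-separated edge list and returns the
#' simplified undirected graph: edge directions are discarded, self-loops
#' and duplicate edges dropped. Lines starting with `%` are comments (the
#' KONECT `out.*` convention). Original node labels are kept as the `name`
#' vertex attribute, so the mapping from internal vertex indices back to
#' input labels is always retrievable via `igraph::V(g)$name`.
#'
#' @param path Path to the edge list file.
#' @param dialect `"plain"` requires exactly two tokens per data line;
#'   `"konect"` accepts the KONECT `out.*` format, where additional columns
#'   (weight, timestamp) may follow the two endpoints and are ignored.
#' @return An undirected simple [igraph][igraph::aaa-igraph-package] graph.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("% comment", "a b", "b a", "b b", "b c"), f)
#' g <- read_edge_list(f, dialect = "konect")
#' igraph::vcount(g)  # 3
#' igraph::gsize(g)   # 2
read_edge_list <- function(path, dialect = c("plain", "konect")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*%", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("empty edge set in ", path)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  ntok <- lengths(toks)
  bad <- if (dialect == "plain") ntok != 2L else ntok < 2L
  if (any(bad)) {
    stop("malformed edge list line ", lineno[which(bad)[1L]],
         ": expected two whitespace-separated node labels")
  }
  ends <- data.frame(from = vapply(toks, `[`, character(1L), 1L),
                     to   = vapply(toks, `[`, character(1L), 2L),
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ends, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::gsize(g) == 0L) stop("empty edge set after simplification in ", path)
  g
}

#' Extract the largest connected component
#'
#' All structural analyses in the package (diameter, closeness, coverage,
#' SIR influence) are run on the largest connected component, where those
#' quantities are well defined.
#'
#' @param g An undirected igraph graph.
#' @return The induced subgraph on the largest component (reindexed).
#' @export
largest_component <- function(g) {
  stopifnot(igraph::vcount(g) >= 1L)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Graph diameter (largest shortest-path length)
#'
#' @param g A connected undirected graph.
#' @return Integer diameter.
#' @export
graph_diameter <- function(g) {
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; extract the largest connected component ",
         "first with largest_component()")
  }
  as.integer(igraph::diameter(g, weights = NA))
}

#' Newman modularity of a node partition
#'
#' Computes \eqn{Q = \sum_c [ l_c/|E| - (d_c/2|E|)^2 ]}, where \eqn{l_c} is
#' the number of intra-community edges and \eqn{d_c} the total degree of
#' community \eqn{c}.
#'
#' @param g An undirected graph with at least one edge.
#' @param membership Community id per node (any vector coercible to a
#'   factor; one entry per vertex).
#' @return The modularity, a real number in \eqn{[-0.5, 1]}.
#' @export
modularity_q <- function(g, membership) {
  n <- igraph::vcount(g)
  m <- igraph::gsize(g)
  if (m == 0L) stop("modularity is undefined on a graph without edges")
  if (length(membership) != n || anyNA(membership)) {
    stop("membership must assign every node to exactly one community")
  }
  comm <- as.integer(factor(membership))
  k <- max(comm)
  el <- igraph::as_edgelist(g, names = FALSE)
  intra <- comm[el[, 1L]] == comm[el[, 2L]]
  l_c <- tabulate(comm[el[, 1L]][intra], nbins = k)
  d_c <- as.numeric(rowsum(igraph::degree(g), comm))
  sum(l_c / m) - sum((d_c / (2 * m))^2)
}

#' Average k-hop coverage
#'
#' The average, over all source nodes, of the fraction of the network lying
#' within BFS distance `k` of the source (the source itself included).
#' Non-decreasing in `k` and exactly 1 once `k` reaches the diameter.
#'
#' @param g A connected undirected graph.
#' @param k Hop count, integer >= 1.
#' @return A real number in (0, 1].
#' @export
khop_coverage <- function(g, k) {
  if (k < 1) stop("k must be >= 1")
  if (!igraph::is_connected(g)) {
    stop("coverage requires a connected graph; use largest_component()")
  }
  n <- igraph::vcount(g)
  mean(igraph::ego_size(g, order = k)) / n
}

#' Summary statistics of a graph
#'
#' @param g A connected undirected graph.
#' @return A list with elements `n`, `m`, `mean_degree`, `diameter`.
#' @export
graph_summary <- function(g) {
  list(n = igraph::vcount(g), m = igraph::gsize(g),
       mean_degree = mean(igraph::degree(g)),
       diameter = graph_diameter(g))
}

#' Write a graph summary as JSON
#'
#' @param g A connected undirected graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_summary <- function(g, path) {
  jsonlite::write_json(graph_summary(g), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
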