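#' Deterministic toy graphs for oracles and examples
#'
#' Named small graphs: `"path_<n>"`, `"cycle_<n>"`, `"star_<n>"` (n nodes,
#' vertex 1 the center), `"complete_<n>"`, `"two_triangles"` (two disjoint
#' triangles, vertex attribute `community` carrying the natural partition),
#' and `"dyad"` (a single edge).
#'
#' @param name Graph name, e.g. `"path_3"`.
#' @return An undirected igraph graph.
#' @export
#' @examples
#' toy_graph("path_3")
#' toy_graph("two_triangles")
toy_graph <- function(name) {
  if (name == "dyad") return(igraph::make_full_graph(2))
  if (name == "two_triangles") {
    g <- igraph::disjoint_union(igraph::make_full_graph(3),
                                igraph::make_full_graph(3))
    igraph::V(g)$community <- rep(1:2, each = 3)
    return(g)
  }
  m <- regmatches(name, regexec("^(path|cycle|star|complete)_([0-9]+)$", name))[[1L]]
  if (length(m) != 3L) stop("unknown toy graph: ", name)
  n <- as.integer(m[3L])
  stopifnot(n >= 1L, n <= 10000L)
  switch(m[2L],
         path = igraph::make_ring(n, circular = FALSE),
         cycle = igraph::make_ring(n, circular = TRUE),
         star = igraph::make_star(n, mode = "undirected"),
         complete = igraph::make_full_graph(n))
}
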