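as_igraph <- function(graph) {
  if (inherits(graph, "gm_graph")) return(graph$graph)
  if (igraph::is_igraph(graph)) return(graph)
  if (is.matrix(graph)) {
    return(igraph::graph_from_adjacency_matrix(graph != 0,
                                               mode = "undirected"))
  }
  stop("expected a gm_graph, igraph, or adjacency matrix")
}

#' Degrees and connectivity density
#'
#' Connectivity density is the proportion of existing connections to the
#' maximum number of possible connections, `2E / (N (N - 1))`.
#'
#' @param graph a `gm_graph`, igraph object, or adjacency matrix.
#' @return List with `degrees` (integer vector) and `density` (scalar in
#'   `[0, 1]`).
#' @export
degree_and_density <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2L) stop("density undefined for fewer than 2 nodes")
  list(degrees = igraph::degree(g),
       density = 2 * igraph::ecount(g) / (n * (n - 1)))
}

#' Local clustering coefficients
#'
#' Watts-Strogatz local clustering: the fraction of a node's neighbour pairs
#' that are themselves connected. Nodes with degree below 2 have no
#' neighbour pairs and get a coefficient of 0.
#'
#' @inheritParams degree_and_density
#' @return List with `local` (per-node coefficients in `[0, 1]`) and `mean`.
#' @export
clustering <- function(graph) {
  g <- as_igraph(graph)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  list(local = ci, mean = mean(ci))
}

#' Shortest-path lengths
#'
#' Breadth-first-search distances on the unweighted graph. Per-node values
#' `L_i` average the finite distances from node `i` to all other nodes; the
#' characteristic path length `L` averages over all connected ordered pairs
#' (pooled, not a mean of per-node means). Infinite distances between
#' components are excluded and counted.
#'
#' @inheritParams degree_and_density
#' @return List with `local` (per-node `L_i`, `NaN` for isolated nodes),
#'   `characteristic` (pooled mean `L`), `n_components`, and
#'   `n_infinite_pairs` (unordered disconnected pairs).
#' @export
path_length <- function(graph) {
  g <- as_igraph(graph)
  d <- igraph::distances(g)
  diag(d) <- NA
  fin <- is.finite(d)
  li <- rowSums(d * fin, na.rm = TRUE) / rowSums(fin, na.rm = TRUE)
  n_inf <- sum(!fin & !is.na(d)) / 2
  list(local = li,
       characteristic = mean(d[fin & !is.na(d)]),
       n_components = igraph::components(g)$no,
       n_infinite_pairs = n_inf)
}

#' Betweenness centrality
#'
#' Number of shortest paths between all unordered node pairs that pass
#' through each node (endpoints excluded), counting a path passing through
#' `v` fractionally when several shortest paths exist. Unnormalized counts.
#'
#' @inheritParams degree_and_density
#' @return Numeric vector of per-node betweenness values (>= 0).
#' @export
betweenness_centrality <- function(graph) {
  g <- as_igraph(graph)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Identify hub nodes from betweenness values
#'
#' A node is a hub when its betweenness centrality lies more than one
#' standard deviation above the mean betweenness (sample SD, n-1
#' denominator). A constant betweenness vector yields no hubs.
#'
#' @param bc numeric vector of betweenness values (length >= 2).
#' @return Logical vector of hub flags.
#' @export
identify_hubs <- function(bc) {
  if (length(bc) < 2L) stop("need at least 2 nodes to define hubs")
  s <- stats::sd(bc)
  if (is.na(s) || s == 0) return(rep(FALSE, length(bc)))
  bc > mean(bc) + s
}

#' Normalize betweenness for graph size
#'
#' Divides each betweenness value by the maximum attainable value in a graph
#' of `n` nodes, `(n - 1)(n - 2) / 2` (the centre of a star), making values
#' comparable across graphs of different size. Optionally rescales the
#' result to `[0, 1]` by min-max for map export.
#'
#' @param bc numeric vector of betweenness values.
#' @param n graph size (>= 3).
#' @param rescale01 if `TRUE`, additionally min-max rescale to `[0, 1]`.
#' @return Numeric vector of normalized values.
#' @export
bc_size_normalize <- function(bc, n, rescale01 = FALSE) {
  if (n < 3L) stop("size normalization needs at least 3 nodes")
  out <- bc / ((n - 1) * (n - 2) / 2)
  if (rescale01) {
    rng <- range(out)
    out <- if (diff(rng) == 0) rep(0, length(out)) else
      (out - rng[1]) / diff(rng)
  }
  out
}

#' Full graph property report
#'
#' Computes every nodal and global property used to characterize a
#' single-subject grey-matter graph: degree, clustering coefficient, average
#' shortest path length, betweenness centrality and hub status per node;
#' size, edge count, connectivity density, means of the nodal properties,
#' and the number of connected components globally.
#'
#' @inheritParams degree_and_density
#' @return An object of class `gm_report`: list with `nodal` (data.frame:
#'   `node`, `degree`, `clustering`, `path_length`, `betweenness`,
#'   `betweenness_norm`, `hub`) and `global` (named list).
#' @export
graph_report <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  dd <- degree_and_density(g)
  cl <- clustering(g)
  pl <- path_length(g)
  bc <- betweenness_centrality(g)
  nodal <- data.frame(
    node = seq_len(n),
    degree = dd$degrees,
    clustering = cl$local,
    path_length = pl$local,
    betweenness = bc,
    betweenness_norm = if (n >= 3) bc_size_normalize(bc, n) else NA_real_,
    hub = identify_hubs(bc)
  )
  global <- list(
    size = n,
    n_edges = igraph::ecount(g),
    density = dd$density,
    mean_degree = mean(dd$degrees),
    mean_clustering = cl$mean,
    char_path_length = pl$characteristic,
    mean_betweenness = mean(bc),
    n_components = pl$n_components,
    n_infinite_pairs = pl$n_infinite_pairs,
    n_hubs = sum(nodal$hub)
  )
  structure(list(nodal = nodal, global = global), class = "gm_report")
}

#' @export
print.gm_report <- function(x, ...) {
  g <- x$global
  cat("<gm_report> N = ", g$size, ", E = ", g$n_edges,
      ", density = ", signif(g$density, 3),
      ", C = ", signif(g$mean_clustering, 3),
      ", L = ", signif(g$char_path_length, 4),
      ", components = ", g$n_components, "\n", sep = "")
  invisible(x)
}
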