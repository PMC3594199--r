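#' Save and load a binary grey-matter graph
#'
#' One self-describing JSON container per subject: a sparse edge list, the
#' node table (cube corner coordinates), and metadata (threshold, achieved
#' spurious proportion, subject id, node count). The round trip is lossless.
#'
#' @param graph a `gm_graph` from [binarize()] or [extract_network()].
#' @param path output path (conventionally `.gmgraph.json`).
#' @return `path`, invisibly.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "gm_graph"))
  el <- igraph::as_edgelist(graph$graph, names = FALSE)
  payload <- list(
    format = "gmnet-graph",
    version = 1L,
    n_nodes = igraph::vcount(graph$graph),
    subject_id = graph$subject_id,
    threshold = graph$threshold,
    achieved_spurious = graph$achieved_spurious,
    nodes = graph$nodes,
    edges = if (nrow(el)) data.frame(from = el[, 1], to = el[, 2]) else
      data.frame(from = integer(0), to = integer(0))
  )
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_graph
#' @return For `load_graph`, the reconstructed `gm_graph`.
#' @export
load_graph <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("corrupt graph file: ",
                                               conditionMessage(e)))
  if (!identical(payload$format, "gmnet-graph")) {
    stop("not a gmnet graph container: ", path)
  }
  n <- payload$n_nodes
  edges <- payload$edges
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges$from)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  nodes <- as.data.frame(payload$nodes)
  for (col in c("x", "y", "z")) {
    if (is.null(nodes[[col]])) nodes[[col]] <- NA_integer_
  }
  structure(
    list(graph = g, nodes = nodes,
         threshold = payload$threshold,
         achieved_spurious = if (is.null(payload$achieved_spurious))
           NA_real_ else payload$achieved_spurious,
         subject_id = if (is.null(payload$subject_id)) NA_character_ else
           payload$subject_id),
    class = "gm_graph"
  )
}
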