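#' Build the co-prescription graph
#'
#' Nodes are the selected drugs, edges the support-selected pairs. Each node
#' gets its degree (incident-edge count) and its average shortest path
#' (unweighted breadth-first distances, averaged over the other nodes of its
#' connected component) — the two topological measures used to size nodes in
#' the network view: drugs prescribed together with many others have high
#' degree and short average paths.
#'
#' @param pairs Tibble of selected pairs (`drug_i`, `drug_j`, `support`, and
#'   optionally `n_cooccur`), e.g. from [mine_frequent_pairs()]. Must be
#'   nonempty.
#' @param drugs Optional character vector of node ids to include even when
#'   isolated (no incident edge); isolated nodes get degree 0 and an infinite
#'   average shortest path.
#' @return A `coprescription_graph`: list with `nodes` (tibble `drug_id`,
#'   `degree`, `avg_shortest_path`), `edges` (the input pairs) and `graph`
#'   (the underlying igraph object).
#' @export
#' @examples
#' pairs <- tibble::tibble(drug_i = c("A", "B"), drug_j = c("B", "C"),
#'                         n_cooccur = c(3L, 2L), support = c(0.3, 0.2))
#' build_coprescription_graph(pairs)$nodes
build_coprescription_graph <- function(pairs, drugs = NULL) {
  if (nrow(pairs) == 0)
    abort("no pairs to graph", class = "oncosepsis_validation_error")
  vertices <- sort(union(union(pairs$drug_i, pairs$drug_j), drugs))
  g <- igraph::graph_from_data_frame(
    pairs[c("drug_i", "drug_j")], directed = FALSE,
    vertices = data.frame(name = vertices))
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  asp <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) Inf else mean(reach)
  })
  nodes <- tibble(drug_id = vertices,
                  degree = as.integer(deg[vertices]),
                  avg_shortest_path = as.numeric(asp[vertices]))
  structure(list(nodes = nodes, edges = pairs, graph = g),
            class = "coprescription_graph")
}

#' @export
print.coprescription_graph <- function(x, ...) {
  cat("<coprescription_graph> ", nrow(x$nodes), " drugs, ",
      nrow(x$edges), " relationships\n", sep = "")
  invisible(x)
}

#' Rank drugs by network centrality
#'
#' Descending by degree, or ascending by average shortest path (a smaller
#' average path means a more central drug); ties are broken
#' lexicographically. Isolated nodes (infinite average path) rank last.
#'
#' @param graph A `coprescription_graph`.
#' @param by `"degree"` or `"avg_shortest_path"`.
#' @return Character vector of drug ids, most central first.
#' @export
rank_nodes <- function(graph, by = c("degree", "avg_shortest_path")) {
  stopifnot(inherits(graph, "coprescription_graph"))
  if (length(by) == 1 && !by %in% c("degree", "avg_shortest_path"))
    abort(paste("unknown ranking key:", by),
          class = "oncosepsis_validation_error")
  by <- match.arg(by)
  n <- graph$nodes
  ord <- if (by == "degree") {
    order(-n$degree, n$drug_id)
  } else {
    order(n$avg_shortest_path, n$drug_id)
  }
  n$drug_id[ord]
}

#' Plot a co-prescription graph
#'
#' Force-directed layout with node size mapped to degree and colour to
#' average shortest path.
#'
#' @param object A `coprescription_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coprescription_graph <- function(object, seed = 1, ...) {
  lay <- withr::with_seed(seed, igraph::layout_with_fr(object$graph))
  nodes <- object$nodes
  nodes$x <- lay[match(nodes$drug_id, igraph::V(object$graph)$name), 1]
  nodes$y <- lay[match(nodes$drug_id, igraph::V(object$graph)$name), 2]
  edges <- object$edges |>
    dplyr::mutate(x = nodes$x[match(.data$drug_i, nodes$drug_id)],
                  y = nodes$y[match(.data$drug_i, nodes$drug_id)],
                  xend = nodes$x[match(.data$drug_j, nodes$drug_id)],
                  yend = nodes$y[match(.data$drug_j, nodes$drug_id)])
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey70", linewidth = 0.3) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = .data$avg_shortest_path)) +
    geom_text(data = nodes,
              aes(x = .data$x, y = .data$y, label = .data$drug_id),
              vjust = -1.1, size = 2.8) +
    scale_size_continuous(range = c(2, 8)) +
    labs(size = "degree", colour = "avg shortest path") +
    theme_void()
}
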