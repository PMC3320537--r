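#' Tidy a semantic graph into its triples tibble
#'
#' @param x A `semantic_graph`.
#' @param compact Compact URIs to prefixed names (default TRUE).
#' @param ... Unused.
#' @return A tibble of triples.
#' @method tidy semantic_graph
#' @export
tidy.semantic_graph <- function(x, compact = TRUE, ...) {
  tt <- x$triples
  if (compact) {
    tt$subject <- compact_uri(tt$subject, x$namespaces)
    tt$predicate <- compact_uri(tt$predicate, x$namespaces)
    tt$object[!tt$is_literal] <- compact_uri(tt$object[!tt$is_literal],
                                             x$namespaces)
  }
  tt
}

#' One-row summary of a semantic graph
#'
#' @param x A `semantic_graph`.
#' @param ... Unused.
#' @return Tibble with triple, instance and predicate counts.
#' @method glance semantic_graph
#' @export
glance.semantic_graph <- function(x, ...) {
  tt <- x$triples
  tibble::tibble(
    n_triples = nrow(tt),
    n_asserted = sum(tt$origin == "asserted"),
    n_inferred = sum(tt$origin == "inferred"),
    n_instances = dplyr::n_distinct(tt$subject[tt$predicate == RDF_TYPE]),
    n_predicates = dplyr::n_distinct(tt$predicate)
  )
}

#' Tidy an ontology schema into its class table
#'
#' @param x An `scb_schema`.
#' @param ... Unused.
#' @return The class tibble (name, parent, definition, external).
#' @method tidy scb_schema
#' @export
tidy.scb_schema <- function(x, ...) x$classes

#' One-row summary of an ontology schema
#'
#' @param x An `scb_schema`.
#' @param ... Unused.
#' @return Tibble with class/property counts, including the size of the
#'   chemogenomic interaction hierarchy.
#' @method glance scb_schema
#' @export
glance.scb_schema <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_properties = nrow(x$properties),
    n_primary = sum(primary_class_names() %in% x$classes$name),
    n_interaction_subclasses =
      sum(interaction_subclass_names() %in% x$classes$name),
    n_chemogenomic = length(descendants(x, "ChemicalProteinInteraction"))
  )
}

#' Tidy an entity graph into its edge list
#'
#' @param x An `entity_graph`.
#' @param ... Unused.
#' @return The edge tibble (from, to, label, score).
#' @method tidy entity_graph
#' @export
tidy.entity_graph <- function(x, ...) x$edges

#' One-row summary of an entity graph
#'
#' @param x An `entity_graph`.
#' @param ... Unused.
#' @return Tibble with node, edge and label counts.
#' @method glance entity_graph
#' @export
glance.entity_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_edge_labels = dplyr::n_distinct(x$edges$label)
  )
}

#' Plot an entity graph
#'
#' Fruchterman-Reingold layout with nodes colored by class and edges by
#' label.
#'
#' @param object An `entity_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entity_graph
#' @export
autoplot.entity_graph <- function(object, ...) {
  ig <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to", "label")], directed = FALSE,
    vertices = object$nodes)
  xy <- igraph::layout_with_fr(ig)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  seg <- object$edges |>
    dplyr::left_join(nodes[, c("uri", "x", "y")], by = c("from" = "uri")) |>
    dplyr::left_join(nodes[, c("uri", "x", "y")], by = c("to" = "uri"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$label),
      alpha = 0.7) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "edge", shape = "node class")
}

#' Plot a shared-drug target ranking
#'
#' @param object An `scb_ranked_targets` tibble.
#' @param top_n Number of top targets to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scb_ranked_targets
#' @export
autoplot.scb_ranked_targets <- function(object, top_n = 10, ...) {
  df <- utils::head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$target, .data$shared_drug_count),
    y = .data$shared_drug_count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "shared disease-linked drugs")
}
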