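# Entity-graph construction and bounded simple-path mining. Interaction
# nodes are contracted to labeled edges between their participants; edges
# are undirected associations whose labels are interaction classes, GO
# annotation sharing, or structural similarity.

#' Build a labeled entity graph from a semantic graph
#'
#' Nodes are instance URIs (physical entities, diseases, side effects);
#' literals and helper nodes (xrefs, outcomes, structures, assays) are
#' excluded. Each binary interaction instance is contracted to one edge
#' between its two participants, labeled by the interaction's asserted
#' (most specific) class; interactions with more participants become a
#' clique with the same label. Proteins sharing at least one GO annotation
#' are joined by a `shares_go_term` edge.
#'
#' @param graph A materialized `semantic_graph`.
#' @param schema An `scb_schema`.
#' @return An `entity_graph`: list of tibbles `nodes` (uri, class, label)
#'   and `edges` (from, to, label, score).
#' @export
build_entity_graph <- function(graph, schema) {
  tt <- graph$triples
  ns <- graph$namespaces
  curi <- function(x) class_uri(schema, x)
  int_classes <- vapply(c("Interaction", descendants(schema, "Interaction")),
                        curi, "")
  types <- tt[tt$predicate == RDF_TYPE & !tt$is_literal, ]
  asserted_types <- types[types$origin == "asserted", ]
  int_nodes <- unique(asserted_types$subject[asserted_types$object %in% int_classes])

  hp <- ro_ns("has_participant")
  part <- tt[tt$predicate == hp & tt$subject %in% int_nodes, c("subject", "object")]

  # entity nodes: participants plus disease nodes linked by disease-gene edges
  dg <- expand_curie("c2b2r:has_disease_gene", ns)
  dgrows <- tt[tt$predicate == dg, ]
  node_uris <- unique(c(part$object, dgrows$subject, dgrows$object))

  labels <- tt[tt$predicate == RDFS_LABEL & tt$subject %in% node_uris, ]
  lab_map <- stats::setNames(labels$object, labels$subject)
  node_class <- asserted_types[asserted_types$subject %in% node_uris, ]
  cls_map <- stats::setNames(compact_uri(node_class$object, ns),
                             node_class$subject)
  nodes <- tibble::tibble(
    uri = sort(node_uris),
    class = unname(cls_map[sort(node_uris)]),
    label = unname(lab_map[sort(node_uris)])
  )

  # contract interactions to participant cliques
  int_label <- asserted_types[asserted_types$subject %in% int_nodes &
                                asserted_types$object %in% int_classes, ]
  ilab_map <- stats::setNames(compact_uri(int_label$object, ns),
                              int_label$subject)
  edges <- part |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe({
      p <- sort(unique(.data$object))
      if (length(p) < 2) {
        tibble::tibble(from = character(), to = character())
      } else {
        cmb <- utils::combn(p, 2)
        tibble::tibble(from = cmb[1, ], to = cmb[2, ])
      }
    }) |>
    dplyr::mutate(label = unname(ilab_map[.data$subject])) |>
    dplyr::select("from", "to", "label") |>
    dplyr::distinct()

  # disease-gene links as labeled edges
  if (nrow(dgrows) > 0) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = pmin(dgrows$subject, dgrows$object),
      to = pmax(dgrows$subject, dgrows$object),
      label = "has_disease_gene"
    ) |> dplyr::distinct())
  }

  # GO-term sharing between proteins
  go <- expand_curie("c2b2r:has_go_annotation", ns)
  gorows <- tt[tt$predicate == go, c("subject", "object")]
  if (nrow(gorows) > 0) {
    shared <- dplyr::inner_join(gorows, gorows, by = "object",
                                relationship = "many-to-many") |>
      dplyr::filter(.data$subject.x < .data$subject.y) |>
      dplyr::distinct(.data$subject.x, .data$subject.y)
    if (nrow(shared) > 0) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = shared$subject.x, to = shared$subject.y,
        label = "shares_go_term"
      ))
      extra <- setdiff(unique(c(shared$subject.x, shared$subject.y)), nodes$uri)
      if (length(extra) > 0) {
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          uri = extra, class = unname(cls_map[extra]),
          label = unname(lab_map[extra])))
      }
    }
  }
  edges$score <- NA_real_
  structure(list(nodes = dplyr::arrange(nodes, .data$uri),
                 edges = dplyr::arrange(edges, .data$from, .data$to, .data$label)),
            class = "entity_graph")
}

#' @export
print.entity_graph <- function(x, ...) {
  cat(sprintf("<entity_graph> %d nodes, %d edges (%d labels)\n",
              nrow(x$nodes), nrow(x$edges), dplyr::n_distinct(x$edges$label)))
  invisible(x)
}

#' Overlay structural-similarity edges
#'
#' Adds undirected `similar_to` edges for compound pairs whose precomputed
#' similarity score reaches the threshold; the score is kept as an edge
#' attribute. Similarity scores are inputs (e.g. fingerprint Tanimoto
#' values computed elsewhere), not computed here.
#'
#' @param g An `entity_graph`.
#' @param pairs Data frame with columns `from`, `to` (compound URIs) and
#'   `score` in [0, 1].
#' @param threshold Minimum score for an edge (default 0.85).
#' @return The augmented `entity_graph`.
#' @export
add_similarity_edges <- function(g, pairs, threshold = 0.85) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) return(g)
  if (any(pairs$score < 0 | pairs$score > 1)) {
    rlang::abort("Similarity scores must lie in [0, 1]",
                 class = "scb_validation_error")
  }
  keep <- pairs[pairs$score >= threshold, ]
  if (nrow(keep) == 0) return(g)
  new_edges <- tibble::tibble(
    from = pmin(keep$from, keep$to),
    to = pmax(keep$from, keep$to),
    label = "similar_to",
    score = keep$score
  ) |> dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)
  g$edges <- dplyr::bind_rows(g$edges, new_edges)
  extra <- setdiff(unique(c(new_edges$from, new_edges$to)), g$nodes$uri)
  if (length(extra) > 0) {
    g$nodes <- dplyr::bind_rows(
      g$nodes,
      tibble::tibble(uri = extra, class = "c2b2r:SmallMolecule",
                     label = NA_character_)
    ) |> dplyr::arrange(.data$uri)
  }
  g
}

#' Enumerate bounded simple paths between two entities
#'
#' Exhaustively enumerates all simple paths (no repeated node) of length at
#' most `max_len` between `a` and `b`, treating edges as undirected
#' associations and keeping each edge's label. Parallel edges with
#' different labels yield distinct paths. Results are ordered by length,
#' then lexicographically by node sequence, then by label sequence.
#'
#' @param g An `entity_graph`.
#' @param a,b Endpoint node URIs (must be present in `g`).
#' @param max_len Maximum path length in edges (default 4).
#' @return Tibble with list-columns `nodes` and `edge_labels`, and integer
#'   `length`.
#' @export
find_paths <- function(g, a, b, max_len = 4) {
  if (!a %in% g$nodes$uri || !b %in% g$nodes$uri) {
    rlang::abort("Path endpoint not present in entity graph",
                 class = "scb_lookup_error")
  }
  stopifnot(max_len >= 1)
  ed <- g$edges
  # undirected adjacency with labels
  adj <- dplyr::bind_rows(
    tibble::tibble(from = ed$from, to = ed$to, label = ed$label),
    tibble::tibble(from = ed$to, to = ed$from, label = ed$label)
  )
  adj_split <- split(adj[, c("to", "label")], adj$from)
  res_nodes <- list(); res_labels <- list()
  path <- character(max_len + 1L); labels <- character(max_len)
  dfs <- function(cur, depth) {
    nb <- adj_split[[cur]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$to[[k]]
      if (nxt == b) {
        res_nodes[[length(res_nodes) + 1L]] <<- c(path[seq_len(depth)], b)
        res_labels[[length(res_labels) + 1L]] <<-
          c(labels[seq_len(depth - 1L)], nb$label[[k]])
        next
      }
      if (depth <= max_len - 1L && !nxt %in% path[seq_len(depth)]) {
        path[depth + 1L] <<- nxt
        labels[depth] <<- nb$label[[k]]
        dfs(nxt, depth + 1L)
      }
    }
  }
  path[1L] <- a
  dfs(a, 1L)
  if (length(res_nodes) == 0) {
    return(tibble::tibble(nodes = list(), edge_labels = list(),
                          length = integer()))
  }
  out <- tibble::tibble(
    nodes = res_nodes, edge_labels = res_labels,
    length = lengths(res_nodes) - 1L
  )
  key_nodes <- vapply(out$nodes, paste, "", collapse = "\r")
  key_labels <- vapply(out$edge_labels, paste, "", collapse = "\r")
  out[order(out$length, key_nodes, key_labels), ]
}
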