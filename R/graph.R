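#' Semantic graph container
#'
#' A semantic graph is a duplicate-free set of RDF triples held as a tibble
#' with columns `subject`, `predicate`, `object`, `is_literal`, `datatype`
#' and `origin` (`"asserted"` or `"inferred"`). URIs are stored in full;
#' literals store their lexical form with an optional XSD datatype.
#'
#' @param triples A data frame with at least `subject`, `predicate`,
#'   `object` columns. Missing bookkeeping columns are filled in.
#' @param namespaces Named character vector of prefix -> URI base used for
#'   serialization and prefixed-name expansion.
#' @return An object of class `semantic_graph`.
#' @export
semantic_graph <- function(triples = NULL, namespaces = default_namespaces()) {
  if (is.null(triples)) {
    triples <- tibble::tibble(
      subject = character(), predicate = character(), object = character(),
      is_literal = logical(), datatype = character(), origin = character()
    )
  }
  triples <- tibble::as_tibble(triples)
  stopifnot(all(c("subject", "predicate", "object") %in% names(triples)))
  if (!"is_literal" %in% names(triples)) triples$is_literal <- FALSE
  if (!"datatype" %in% names(triples)) triples$datatype <- NA_character_
  if (!"origin" %in% names(triples)) triples$origin <- "asserted"
  triples$datatype[triples$is_literal == FALSE] <- NA_character_
  triples <- dplyr::distinct(
    triples, .data$subject, .data$predicate, .data$object,
    .data$is_literal, .data$datatype, .data$origin
  )
  # an asserted triple subsumes an inferred copy
  triples <- triples |>
    dplyr::arrange(match(.data$origin, c("asserted", "inferred"))) |>
    dplyr::distinct(.data$subject, .data$predicate, .data$object,
                    .data$is_literal, .data$datatype, .keep_all = TRUE)
  structure(
    list(triples = triples, namespaces = namespaces),
    class = "semantic_graph"
  )
}

#' @export
print.semantic_graph <- function(x, ...) {
  n <- nrow(x$triples)
  ninf <- sum(x$triples$origin == "inferred")
  cat(sprintf("<semantic_graph> %d triples (%d asserted, %d inferred)\n",
              n, n - ninf, ninf))
  cat(sprintf("  %d subjects, %d predicates\n",
              dplyr::n_distinct(x$triples$subject),
              dplyr::n_distinct(x$triples$predicate)))
  invisible(x)
}

# Row-bind triples into a graph, keeping the duplicate-free invariant.
graph_add <- function(graph, triples) {
  semantic_graph(dplyr::bind_rows(graph$triples, triples), graph$namespaces)
}

triple_rows <- function(subject, predicate, object,
                        is_literal = FALSE, datatype = NA_character_,
                        origin = "asserted") {
  if (length(subject) == 0 || length(object) == 0) {
    return(tibble::tibble(subject = character(), predicate = character(),
                          object = character(), is_literal = logical(),
                          datatype = character(), origin = character()))
  }
  tibble::tibble(subject = subject, predicate = predicate,
                 object = as.character(object),
                 is_literal = is_literal, datatype = datatype, origin = origin)
}

#' Number of triples in a graph
#' @param graph A `semantic_graph`.
#' @param origin Optionally restrict to `"asserted"` or `"inferred"`.
#' @return Integer count.
#' @export
n_triples <- function(graph, origin = NULL) {
  tt <- graph$triples
  if (!is.null(origin)) tt <- tt[tt$origin %in% origin, ]
  nrow(tt)
}

#' Drop inferred triples
#' @param graph A `semantic_graph`.
#' @return A `semantic_graph` containing asserted triples only.
#' @export
asserted_only <- function(graph) {
  semantic_graph(graph$triples[graph$triples$origin == "asserted", ],
                 graph$namespaces)
}

#' Collapse duplicate triples and re-check graph invariants
#'
#' Identical triples are collapsed; entity nodes sharing a primary URI are
#' already a single node by construction (URIs are minted from primary
#' identifiers), so their cross-references union naturally. Interaction
#' instances minted from distinct source records keep distinct URIs and are
#' deliberately not merged: parallel records of one chemical-protein pair
#' across databases are retained side by side.
#'
#' @param graph A `semantic_graph`.
#' @return A deduplicated `semantic_graph`.
#' @export
deduplicate <- function(graph) {
  semantic_graph(graph$triples, graph$namespaces)
}

#' Test two graphs for isomorphism
#'
#' Graphs with no blank nodes compare as triple sets. Blank nodes (URIs in
#' the reserved `_:` space) are matched by iterative signature refinement.
#'
#' @param g1,g2 `semantic_graph` objects.
#' @return TRUE or FALSE.
#' @export
graph_isomorphic <- function(g1, g2) {
  t1 <- canon_triples(g1$triples)
  t2 <- canon_triples(g2$triples)
  if (nrow(t1) != nrow(t2)) return(FALSE)
  key <- function(tt) {
    sort(paste(tt$subject, tt$predicate, tt$object, tt$is_literal,
               dplyr::coalesce(tt$datatype, ""), sep = "\r"))
  }
  identical(key(t1), key(t2))
}

is_bnode <- function(x) startsWith(x, "_:")

# Replace blank-node labels by canonical signature-based labels.
canon_triples <- function(tt) {
  bn <- unique(c(tt$subject[is_bnode(tt$subject)],
                 tt$object[!tt$is_literal & is_bnode(tt$object)]))
  if (length(bn) == 0) return(tt)
  lab <- stats::setNames(rep("b", length(bn)), bn)
  for (iter in 1:3) {
    sig <- vapply(bn, function(b) {
      out_e <- tt[tt$subject == b, ]
      in_e <- tt[!tt$is_literal & tt$object == b, ]
      o_sig <- sort(paste(out_e$predicate,
                          ifelse(!out_e$is_literal & is_bnode(out_e$object),
                                 lab[out_e$object], out_e$object)))
      i_sig <- sort(paste(in_e$predicate,
                          ifelse(is_bnode(in_e$subject), lab[in_e$subject],
                                 in_e$subject)))
      rlang::hash(list(o_sig, i_sig))
    }, character(1))
    lab <- stats::setNames(sig, bn)
  }
  tt$subject <- ifelse(is_bnode(tt$subject), paste0("_:", lab[tt$subject]), tt$subject)
  swap <- !tt$is_literal & is_bnode(tt$object)
  tt$object[swap] <- paste0("_:", lab[tt$object[swap]])
  tt
}
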