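#' Materialize inferred triples
#'
#' Forward-chains a fixed RDFS-plus rule set to its least fixpoint:
#'
#' * type propagation via the schema subclass hierarchy,
#' * subproperty propagation (when declared),
#' * inverse-property completion (e.g. `has_participant` /
#'   `participates_in`),
#' * transitive closure of transitive properties (e.g. the disease
#'   hierarchy),
#' * domain/range typing from property declarations.
#'
#' The output contains the input; re-running adds nothing (idempotent).
#' Inferred triples carry `origin = "inferred"` so exports can include or
#' exclude them. Instances typed by a class absent from the schema are left
#' un-propagated with a warning.
#'
#' @param graph A `semantic_graph`.
#' @param schema An `scb_schema`.
#' @return The materialized `semantic_graph`.
#' @export
materialize <- function(graph, schema) {
  ns <- schema$namespaces
  cl <- schema$classes
  curi <- function(x) class_uri(schema, x)

  # class URI -> vector of (strict) superclass URIs
  sup_map <- new.env(parent = emptyenv())
  for (nm in cl$name) {
    sup_map[[curi(nm)]] <- vapply(ancestors(schema, nm), curi, "")
  }

  pr <- schema$properties
  puri <- expand_curie(pr$name, ns)
  inv_uri <- ifelse(is.na(pr$inverse), NA_character_,
                    expand_curie(ifelse(is.na(pr$inverse), "rdfs:label",
                                        pr$inverse), ns))
  inv_map <- stats::setNames(inv_uri, puri)
  inv_map <- inv_map[!is.na(inv_map)]
  trans_props <- puri[pr$transitive]
  sub_map <- if ("parent" %in% names(pr)) {
    ok <- !is.na(pr$parent)
    stats::setNames(expand_curie(pr$parent[ok], ns), puri[ok])
  } else c()
  dom_map <- stats::setNames(
    ifelse(is.na(pr$domain), NA_character_, vapply(
      ifelse(is.na(pr$domain), "Interaction", pr$domain), curi, "")), puri)
  dom_map <- dom_map[!is.na(pr$domain)]
  rng <- pr$kind == "object" & !is.na(pr$range)
  rng_map <- stats::setNames(vapply(ifelse(rng, pr$range, "Interaction")[rng],
                                    curi, ""), puri[rng])

  tt <- graph$triples
  unknown <- unique(tt$object[tt$predicate == RDF_TYPE &
                                startsWith(tt$object, unname(ns[["c2b2r"]])) &
                                !tt$object %in% ls(sup_map)])
  if (length(unknown) > 0) {
    rlang::warn(paste0("Instances typed by classes absent from schema: ",
                       paste(compact_uri(unknown, ns), collapse = ", ")))
  }

  known <- paste(tt$subject, tt$predicate, tt$object, tt$is_literal, sep = "\r")
  new_rows <- tt
  repeat {
    cand <- list()
    # type propagation via subclass
    ty <- new_rows[new_rows$predicate == RDF_TYPE & !new_rows$is_literal, ]
    if (nrow(ty) > 0) {
      sups <- lapply(ty$object, function(o) sup_map[[o]] %||% character())
      nper <- lengths(sups)
      if (sum(nper) > 0) {
        cand[[length(cand) + 1L]] <- triple_rows(
          rep(ty$subject, nper), RDF_TYPE, unlist(sups), origin = "inferred")
      }
    }
    obj <- new_rows[!new_rows$is_literal, ]
    # subproperty propagation
    sp <- obj[obj$predicate %in% names(sub_map), ]
    if (nrow(sp) > 0) {
      cand[[length(cand) + 1L]] <- triple_rows(
        sp$subject, unname(sub_map[sp$predicate]), sp$object, origin = "inferred")
    }
    # inverse completion
    iv <- obj[obj$predicate %in% names(inv_map), ]
    if (nrow(iv) > 0) {
      cand[[length(cand) + 1L]] <- triple_rows(
        iv$object, unname(inv_map[iv$predicate]), iv$subject, origin = "inferred")
    }
    # transitive closure: join new edges against all edges of the property
    for (tp in trans_props) {
      newe <- new_rows[!new_rows$is_literal & new_rows$predicate == tp, ]
      alle <- tt[!tt$is_literal & tt$predicate == tp, ]
      if (nrow(newe) > 0 && nrow(alle) > 0) {
        j1 <- dplyr::inner_join(newe[, c("subject", "object")],
                                alle[, c("subject", "object")],
                                by = c("object" = "subject"),
                                relationship = "many-to-many")
        j2 <- dplyr::inner_join(alle[, c("subject", "object")],
                                newe[, c("subject", "object")],
                                by = c("object" = "subject"),
                                relationship = "many-to-many")
        both <- dplyr::bind_rows(
          tibble::tibble(subject = j1$subject, object = j1$object.y),
          tibble::tibble(subject = j2$subject, object = j2$object.y)
        )
        both <- both[both$subject != both$object, ]
        if (nrow(both) > 0) {
          cand[[length(cand) + 1L]] <- triple_rows(
            both$subject, tp, both$object, origin = "inferred")
        }
      }
    }
    # domain / range typing
    dm <- obj[obj$predicate %in% names(dom_map), ]
    if (nrow(dm) > 0) {
      cand[[length(cand) + 1L]] <- triple_rows(
        dm$subject, RDF_TYPE, unname(dom_map[dm$predicate]), origin = "inferred")
    }
    rg <- obj[obj$predicate %in% names(rng_map), ]
    if (nrow(rg) > 0) {
      cand[[length(cand) + 1L]] <- triple_rows(
        rg$object, RDF_TYPE, unname(rng_map[rg$predicate]), origin = "inferred")
    }
    if (length(cand) == 0) break
    cand <- dplyr::distinct(dplyr::bind_rows(cand),
                            .data$subject, .data$predicate, .data$object,
                            .keep_all = TRUE)
    keys <- paste(cand$subject, cand$predicate, cand$object, cand$is_literal,
                  sep = "\r")
    fresh <- !keys %in% known
    if (!any(fresh)) break
    new_rows <- cand[fresh, ]
    known <- c(known, keys[fresh])
    tt <- dplyr::bind_rows(tt, new_rows)
  }
  semantic_graph(tt, graph$namespaces)
}
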