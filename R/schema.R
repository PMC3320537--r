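#' Build the systems chemical biology ontology schema
#'
#' Constructs the class/property schema: nine primary classes (SmallMolecule,
#' Drug, Protein, BioAssay, Disease, SideEffect, Literature, Pathway,
#' Interaction), five Interaction subclasses, a 61-class chemogenomic
#' interaction hierarchy under ChemicalProteinInteraction split into
#' chemical-regulates-protein and protein-regulates-chemical branches, and
#' the utility classes that carry structure, provenance, assay-outcome and
#' physical-property payloads. Building is deterministic: the same
#' configuration always yields an identical schema.
#'
#' @param config Optional list. Recognized keys: `namespaces` (a list with
#'   `base`, the ontology namespace URI) and `extra_classes` (a data frame
#'   with `name`/`parent` columns appended to the class table).
#' @return An object of class `scb_schema` with tibbles `classes` and
#'   `properties` and a named `namespaces` vector.
#' @examples
#' sc <- build_schema()
#' nrow(descendants(sc, "ChemicalProteinInteraction"))
#' @export
build_schema <- function(config = NULL) {
  base <- scb_base_uri()
  if (!is.null(config)) {
    if (!is.list(config)) {
      rlang::abort("config must be a list", class = "scb_config_error")
    }
    known <- c("namespaces", "extra_classes")
    bad <- setdiff(names(config), known)
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown configuration key: ", bad[[1]]),
                   class = "scb_config_error")
    }
    if (!is.null(config$namespaces)) {
      if (!is.list(config$namespaces) || is.null(config$namespaces$base) ||
          !is.character(config$namespaces$base)) {
        rlang::abort("Malformed configuration key: namespaces.base",
                     class = "scb_config_error")
      }
      base <- config$namespaces$base
    }
  }
  classes <- base_class_table()
  if (!is.null(config$extra_classes)) {
    extra <- tibble::as_tibble(config$extra_classes)
    if (!all(c("name", "parent") %in% names(extra))) {
      rlang::abort("Malformed configuration key: extra_classes",
                   class = "scb_config_error")
    }
    if (!"definition" %in% names(extra)) extra$definition <- NA_character_
    if (!"external" %in% names(extra)) extra$external <- NA_character_
    classes <- dplyr::bind_rows(classes, extra)
  }
  schema <- structure(
    list(
      classes = classes,
      properties = base_property_table(),
      namespaces = default_namespaces(base)
    ),
    class = "scb_schema"
  )
  validate_schema(schema)
  schema
}

#' @export
print.scb_schema <- function(x, ...) {
  cat(sprintf("<scb_schema> %d classes, %d properties\n",
              nrow(x$classes), nrow(x$properties)))
  cat("  base namespace:", unname(x$namespaces[["c2b2r"]]), "\n")
  invisible(x)
}

# Hard invariants: unique names, resolvable parents, acyclicity (topological
# sort), symmetric inverses, no inverse on data properties, the fixed class
# counts of the ontology.
validate_schema <- function(schema) {
  cl <- schema$classes
  if (anyDuplicated(cl$name)) {
    rlang::abort(paste0("Duplicate class name: ",
                        cl$name[duplicated(cl$name)][[1]]),
                 class = "scb_schema_error")
  }
  unresolved <- setdiff(stats::na.omit(cl$parent), cl$name)
  if (length(unresolved) > 0) {
    rlang::abort(paste0("Parent class not declared: ", unresolved[[1]]),
                 class = "scb_schema_error")
  }
  # topological sort over the subclass graph detects cycles
  g <- igraph::graph_from_data_frame(
    cl[!is.na(cl$parent), c("name", "parent")],
    directed = TRUE,
    vertices = cl["name"]
  )
  if (!igraph::is_dag(g)) {
    rlang::abort("Subclass graph contains a cycle", class = "scb_schema_error")
  }
  pr <- schema$properties
  if (any(pr$kind == "data" & !is.na(pr$inverse))) {
    rlang::abort("Data properties cannot declare an inverse",
                 class = "scb_schema_error")
  }
  obj <- pr[pr$kind == "object", ]
  withinv <- obj[!is.na(obj$inverse), ]
  for (i in seq_len(nrow(withinv))) {
    other <- obj[obj$name == withinv$inverse[[i]], ]
    if (nrow(other) != 1 || is.na(other$inverse) ||
        other$inverse != withinv$name[[i]]) {
      rlang::abort(paste0("Inverse not declared symmetrically: ",
                          withinv$name[[i]]),
                   class = "scb_schema_error")
    }
  }
  stopifnot(all(primary_class_names() %in% cl$name))
  invisible(schema)
}

#' Transitive subclass descendants of a class
#'
#' @param schema An `scb_schema`.
#' @param class Class name (term identifier, e.g. `"Interaction"`).
#' @return Character vector of all classes strictly below `class`.
#' @export
descendants <- function(schema, class) {
  cl <- schema$classes
  if (!class %in% cl$name) {
    rlang::abort(paste0("Unknown class: ", class), class = "scb_lookup_error")
  }
  out <- character()
  frontier <- class
  while (length(frontier) > 0) {
    kids <- cl$name[!is.na(cl$parent) & cl$parent %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  sort(out)
}

#' Transitive subclass ancestors of a class
#' @inheritParams descendants
#' @return Character vector of all classes strictly above `class`.
#' @export
ancestors <- function(schema, class) {
  cl <- schema$classes
  if (!class %in% cl$name) {
    rlang::abort(paste0("Unknown class: ", class), class = "scb_lookup_error")
  }
  out <- character()
  cur <- class
  repeat {
    p <- cl$parent[cl$name == cur]
    if (length(p) == 0 || is.na(p)) break
    if (p %in% out) break
    out <- c(out, p)
    cur <- p
  }
  out
}

# Full class URI for a schema term.
class_uri <- function(schema, class) {
  c2b2r(class, base = unname(schema$namespaces[["c2b2r"]]))
}

# Expand a property's prefixed name using the schema namespaces.
property_uri <- function(schema, name) {
  expand_curie(name, schema$namespaces)
}

#' Express the schema as RDF triples
#'
#' Classes become `owl:Class` declarations with `rdfs:subClassOf` axioms and
#' `rdfs:comment` definitions; external vocabulary mappings are kept as
#' annotation literals (`rdfs:seeAlso`), not imports. Properties become
#' `owl:ObjectProperty`/`owl:DatatypeProperty` nodes with domain, range,
#' `owl:inverseOf` and `owl:TransitiveProperty` axioms.
#'
#' @param schema An `scb_schema`.
#' @return A `semantic_graph` of the terminology.
#' @export
schema_to_graph <- function(schema) {
  ns <- schema$namespaces
  cl <- schema$classes
  curi <- function(x) class_uri(schema, x)
  tt <- list(
    triple_rows(curi(cl$name), RDF_TYPE, owl_ns("Class")),
    triple_rows(curi(cl$name), RDFS_LABEL, cl$name, is_literal = TRUE,
                datatype = xsd_ns("string"))
  )
  has_def <- !is.na(cl$definition)
  tt <- c(tt, list(
    triple_rows(curi(cl$name[has_def]), rdfs_ns("comment"), cl$definition[has_def],
                is_literal = TRUE, datatype = xsd_ns("string"))
  ))
  has_par <- !is.na(cl$parent)
  tt <- c(tt, list(
    triple_rows(curi(cl$name[has_par]), RDFS_SUBCLASSOF, curi(cl$parent[has_par]))
  ))
  has_ext <- !is.na(cl$external)
  tt <- c(tt, list(
    triple_rows(curi(cl$name[has_ext]), rdfs_ns("seeAlso"), cl$external[has_ext],
                is_literal = TRUE, datatype = xsd_ns("string"))
  ))
  pr <- schema$properties
  puri <- expand_curie(pr$name, ns)
  ptype <- ifelse(pr$kind == "object", owl_ns("ObjectProperty"),
                  owl_ns("DatatypeProperty"))
  tt <- c(tt, list(triple_rows(puri, RDF_TYPE, ptype)))
  hd <- !is.na(pr$domain)
  tt <- c(tt, list(triple_rows(puri[hd], rdfs_ns("domain"), curi(pr$domain[hd]))))
  hr <- !is.na(pr$range)
  rng <- ifelse(pr$kind[hr] == "data", expand_curie(pr$range[hr], ns),
                curi(pr$range[hr]))
  tt <- c(tt, list(triple_rows(puri[hr], rdfs_ns("range"), rng)))
  hi <- !is.na(pr$inverse)
  tt <- c(tt, list(triple_rows(puri[hi], owl_ns("inverseOf"),
                               expand_curie(pr$inverse[hi], ns))))
  ht <- pr$transitive
  tt <- c(tt, list(triple_rows(puri[ht], RDF_TYPE, owl_ns("TransitiveProperty"))))
  semantic_graph(dplyr::bind_rows(tt), ns)
}

#' Serialize the schema as an OWL document
#'
#' @param schema An `scb_schema`.
#' @param format `"turtle"` or `"rdfxml"`.
#' @param file Optional path; when omitted the document is returned as a
#'   character string.
#' @return The document text (invisibly when written to `file`).
#' @export
serialize_schema <- function(schema, format = c("turtle", "rdfxml"), file = NULL) {
  if (!is.character(format) || !all(format %in% c("turtle", "rdfxml"))) {
    rlang::abort(paste0("Unsupported serialization format: ",
                        paste(format, collapse = ", ")),
                 class = "scb_format_error")
  }
  format <- match.arg(format)
  write_graph(schema_to_graph(schema), format = format, file = file)
}
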