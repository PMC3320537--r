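# Annotation pipeline: mapped source tables -> ontology-conformant RDF
# instances. Interactions are first-class nodes carrying participants,
# evidence, outcomes and provenance.

# Stable skolem URI for helper nodes (xrefs, outcomes, structures): hash of
# the parent URI plus content, so identical content collapses to one node
# and diffs are deterministic.
skolem_uri <- function(base, prefix, ...) {
  paste0(base, prefix, substr(rlang::hash(paste(..., sep = "\r")), 1, 16))
}

#' Read a column-mapping table from YAML
#'
#' The mapping declares, per source table, the record kind, the identifier
#' column and how each column maps to an ontology term or structural role
#' (cross-reference, participant, outcome field, publication, structure
#' representation).
#'
#' @param path Path to a YAML file (or a YAML string).
#' @return The mapping list.
#' @export
read_mapping <- function(path) {
  m <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(m$sources)) {
    rlang::abort("Mapping must declare a 'sources' key", class = "scb_config_error")
  }
  m
}

# Column roles understood by the annotator besides direct property terms.
mapping_roles <- c(
  "xref", "inchi", "structure", "label",
  "participant_chemical", "participant_protein", "participant_drug",
  "participant_disease", "participant_side_effect",
  "interaction_class", "assay_description",
  "outcome_measurement", "outcome_relation", "outcome_value", "outcome_unit",
  "publication", "publication_title", "go_terms"
)

entity_kinds <- c("compound", "drug", "protein", "side_effect", "pathway")
interaction_kinds <- c(
  "chemical_protein_interaction", "drug_disease", "drug_side_effect",
  "drug_treatment", "protein_protein_interaction", "drug_drug_interaction",
  "disease_gene"
)

#' Validate a mapping table against the schema
#'
#' Every mapped ontology term (interaction class or property) must exist in
#' the schema; unknown roles or classes are configuration errors.
#'
#' @param mapping Mapping list (see [read_mapping()]).
#' @param schema An `scb_schema`.
#' @return The mapping, invisibly.
#' @export
validate_mapping <- function(mapping, schema) {
  for (src in names(mapping$sources)) {
    sm <- mapping$sources[[src]]
    if (is.null(sm$kind) ||
        !sm$kind %in% c(entity_kinds, interaction_kinds)) {
      rlang::abort(paste0("Unknown record kind for source ", src, ": ",
                          sm$kind %||% "<missing>"),
                   class = "scb_config_error")
    }
    if (!is.null(sm$class) && !sm$class %in% schema$classes$name) {
      rlang::abort(paste0("Mapped class not in schema: ", sm$class),
                   class = "scb_config_error")
    }
    for (col in names(sm$columns)) {
      cm <- sm$columns[[col]]
      term <- cm$term %||% cm
      if (term %in% mapping_roles) {
        if (identical(term, "interaction_class")) {
          vals <- unlist(cm$values)
          bad <- setdiff(vals, schema$classes$name)
          if (length(bad) > 0) {
            rlang::abort(paste0("Mapped interaction class not in schema: ",
                                bad[[1]]), class = "scb_config_error")
          }
        }
        next
      }
      if (!term %in% c("rdfs:label", schema$properties$name)) {
        rlang::abort(paste0("Mapped term not in schema: ", term),
                     class = "scb_config_error")
      }
    }
  }
  invisible(mapping)
}

# columns of a source mapping having a given role
cols_with_role <- function(sm, role) {
  names(sm$columns)[vapply(sm$columns, function(cm) {
    identical(cm$term %||% cm, role)
  }, logical(1))]
}

col_value <- function(row, col) {
  if (!col %in% names(row)) return(NA_character_)
  v <- as.character(row[[col]])
  if (length(v) == 0 || is.na(v) || !nzchar(v)) NA_character_ else v
}

literal_num <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (is.na(num)) {
    list(value = x, datatype = xsd_ns("string"))
  } else {
    list(value = x, datatype = xsd_ns("double"))
  }
}

#' Annotate source tables into a semantic graph
#'
#' Each entity record becomes a typed instance with label, data properties,
#' structure representations and UnificationXref provenance nodes; each
#' interaction record becomes a first-class interaction node linked by
#' `ro:has_participant` to its resolved participants, with bioassay
#' evidence, outcome quadruples and publication references when present.
#' Records whose participants cannot be resolved are skipped with a logged
#' reason. Output is deterministic given fixed inputs.
#'
#' @param sources Named list of data frames, one per source table; names
#'   must match the mapping's source names.
#' @param mapping Mapping list (see [read_mapping()]).
#' @param schema An `scb_schema`.
#' @param ctx A `resolution_context`.
#' @param quiet Suppress skip/unmapped-column messages.
#' @return A `semantic_graph`.
#' @export
annotate <- function(sources, mapping, schema, ctx = resolution_context(),
                     quiet = TRUE) {
  validate_mapping(mapping, schema)
  base <- ctx$base
  ns <- schema$namespaces
  acc <- list()
  add <- function(tt) acc[[length(acc) + 1L]] <<- tt

  curi <- function(cls) class_uri(schema, cls)
  puri <- function(p) expand_curie(p, ns)

  # registry of resolved entities so interaction records can reference them
  compounds <- new.env(parent = emptyenv())  # by CID and by inchi

  # entity sources first, so participants resolve against known compounds
  src_order <- names(mapping$sources)
  kinds <- vapply(src_order, function(s) mapping$sources[[s]]$kind, character(1))
  src_order <- src_order[order(kinds %in% interaction_kinds)]

  for (src in src_order) {
    sm <- mapping$sources[[src]]
    df <- sources[[src]]
    if (is.null(df)) next
    df <- tibble::as_tibble(df)
    unmapped <- setdiff(names(df), names(sm$columns))
    if (length(unmapped) > 0 && !quiet) {
      rlang::inform(paste0("Source ", src, ": unmapped columns skipped: ",
                           paste(unmapped, collapse = ", ")))
    }
    id_col <- sm$id_column %||% NA_character_
    for (r in seq_len(nrow(df))) {
      row <- df[r, ]
      rec_id <- if (!is.na(id_col)) col_value(row, id_col) else as.character(r)
      if (is.na(rec_id)) rec_id <- as.character(r)
      if (sm$kind %in% entity_kinds) {
        add(annotate_entity(row, src, sm, schema, ctx, compounds, curi, puri))
      } else {
        tt <- annotate_interaction(row, src, sm, rec_id, schema, ctx,
                                   compounds, curi, puri, quiet)
        if (!is.null(tt)) add(tt)
      }
    }
  }

  # disease hierarchy from the term table: typed nodes + transitive parents
  if (!is.null(ctx$do_terms)) {
    dt <- ctx$do_terms
    duri <- vapply(dt$doid, mint_uri, "", kind = "disease", base = base)
    add(triple_rows(duri, RDF_TYPE, curi("Disease")))
    add(triple_rows(duri, RDFS_LABEL, dt$label, is_literal = TRUE,
                    datatype = xsd_ns("string")))
    add(triple_rows(duri, puri("c2b2r:DOID"), dt$doid, is_literal = TRUE,
                    datatype = xsd_ns("string")))
    hasp <- !is.na(dt$parent_doid) & nzchar(dt$parent_doid)
    if (any(hasp)) {
      add(triple_rows(duri[hasp], puri("c2b2r:subDiseaseOf"),
                      vapply(dt$parent_doid[hasp], mint_uri, "",
                             kind = "disease", base = base)))
    }
  }

  if (length(acc) == 0) return(semantic_graph(NULL, ns))
  semantic_graph(dplyr::bind_rows(acc), ns)
}

# ---- entity records ----------------------------------------------------

annotate_entity <- function(row, src, sm, schema, ctx, compounds, curi, puri) {
  base <- ctx$base
  xref_cols <- cols_with_role(sm, "xref")
  xr <- dplyr::bind_rows(lapply(xref_cols, function(col) {
    v <- col_value(row, col)
    if (is.na(v)) return(NULL)
    xref(sm$columns[[col]]$db, v)
  }))
  inchi_col <- cols_with_role(sm, "inchi")
  inchi <- if (length(inchi_col) > 0) col_value(row, inchi_col[[1]]) else NA_character_
  if (is.na(inchi)) inchi <- NULL

  ent <- switch(sm$kind,
    compound = resolve_compound(xr, inchi, ctx),
    drug = ,
    protein = ,
    side_effect = ,
    pathway = {
      idv <- col_value(row, sm$id_column)
      resolve_native(sm$kind, idv, ctx, xrefs = xr)
    }
  )
  uri <- ent$uri[[1]]
  if (sm$kind == "compound") {
    compounds[[paste0("cid:", ent$primary_id[[1]])]] <- uri
    if (!is.null(inchi)) compounds[[paste0("inchi:", inchi)]] <- uri
    for (k in seq_len(nrow(xr))) {
      if (tolower(xr$db[[k]]) == "pubchem") {
        compounds[[paste0("cid:", xr$id[[k]])]] <-
          compounds[[paste0("cid:", xr$id[[k]])]] %||% uri
      }
    }
  }
  cls <- sm$class %||% switch(sm$kind,
    compound = "SmallMolecule", drug = "Drug", protein = "Protein",
    side_effect = "SideEffect", pathway = "Pathway"
  )
  tt <- list(triple_rows(uri, RDF_TYPE, curi(cls)))
  for (col in names(sm$columns)) {
    cm <- sm$columns[[col]]
    term <- cm$term %||% cm
    v <- col_value(row, col)
    if (is.na(v)) next
    if (term %in% c("label", "rdfs:label")) {
      tt <- c(tt, list(triple_rows(uri, RDFS_LABEL, v, is_literal = TRUE,
                                   datatype = xsd_ns("string"))))
    } else if (term == "structure") {
      tt <- c(tt, list(structure_rows(uri, cm$format, v, base, curi, puri)))
    } else if (term == "inchi") {
      tt <- c(tt, list(structure_rows(uri, "inchi", v, base, curi, puri)))
    } else if (term == "c2b2r:molecularWeight") {
      pp <- skolem_uri(base, "physprop", uri, "molecularWeight")
      lit <- literal_num(v)
      tt <- c(tt, list(
        triple_rows(uri, puri("c2b2r:hasPhysicalProperty"), pp),
        triple_rows(pp, RDF_TYPE, curi("PhysicalProperty")),
        triple_rows(pp, puri("c2b2r:molecularWeight"), lit$value,
                    is_literal = TRUE, datatype = lit$datatype)
      ))
    } else if (term == "go_terms") {
      gos <- strsplit(v, "|", fixed = TRUE)[[1]]
      gouri <- paste0("http://purl.obolibrary.org/obo/",
                      gsub(":", "_", gos, fixed = TRUE))
      tt <- c(tt, list(triple_rows(uri, puri("c2b2r:has_go_annotation"), gouri)))
    } else if (term == "xref") {
      # handled above via resolution; emit the provenance node
    } else {
      dp <- schema$properties[schema$properties$name == term, ]
      if (nrow(dp) == 1 && dp$kind == "data" &&
          identical(dp$range, "xsd:double")) {
        lit <- literal_num(v)
        tt <- c(tt, list(triple_rows(uri, puri(term), lit$value,
                                     is_literal = TRUE, datatype = lit$datatype)))
      } else {
        tt <- c(tt, list(triple_rows(uri, puri(term), v, is_literal = TRUE,
                                     datatype = xsd_ns("string"))))
      }
    }
  }
  if (sm$kind == "compound") {
    tt <- c(tt, list(triple_rows(uri, puri("c2b2r:CID"), ent$primary_id[[1]],
                                 is_literal = TRUE,
                                 datatype = xsd_ns("integer"))))
  }
  tt <- c(tt, list(xref_node_rows(uri, xr, "UnificationXref", base, curi, puri)))
  dplyr::bind_rows(tt)
}

structure_rows <- function(uri, format, data, base, curi, puri) {
  snode <- skolem_uri(base, "structure", uri, format, data)
  dplyr::bind_rows(
    triple_rows(uri, bp_ns("structure"), snode),
    triple_rows(snode, RDF_TYPE, curi("ChemicalStructure")),
    triple_rows(snode, bp_ns("structureFormat"), format, is_literal = TRUE,
                datatype = xsd_ns("string")),
    triple_rows(snode, bp_ns("structureData"), data, is_literal = TRUE,
                datatype = xsd_ns("string"))
  )
}

xref_node_rows <- function(uri, xr, class, base, curi, puri) {
  if (is.null(xr) || nrow(xr) == 0) {
    return(triple_rows(character(), "p", character()))
  }
  xr <- dplyr::distinct(xr, .data$db, .data$id, .keep_all = TRUE)
  nodes <- unname(mapply(function(db, id) skolem_uri(base, "xref", class, db, id),
                         xr$db, xr$id))
  tt <- dplyr::bind_rows(
    triple_rows(uri, bp_ns("xref"), nodes),
    triple_rows(nodes, RDF_TYPE, curi(class)),
    triple_rows(nodes, puri("c2b2r:DB"), xr$db, is_literal = TRUE,
                datatype = xsd_ns("string")),
    triple_rows(nodes, puri("c2b2r:ID"), xr$id, is_literal = TRUE,
                datatype = xsd_ns("string"))
  )
  hasc <- "comments" %in% names(xr) & !is.na(xr$comments)
  if (any(hasc)) {
    tt <- dplyr::bind_rows(tt,
      triple_rows(nodes[hasc], puri("c2b2r:comments"), xr$comments[hasc],
                  is_literal = TRUE, datatype = xsd_ns("string")))
  }
  tt
}

# ---- interaction records -----------------------------------------------

annotate_interaction <- function(row, src, sm, rec_id, schema, ctx,
                                 compounds, curi, puri, quiet) {
  base <- ctx$base
  participants <- list()
  skip <- function(why) {
    if (!quiet) rlang::inform(paste0("Skipping ", src, "/", rec_id, ": ", why),
                              class = "scb_skipped_record")
    NULL
  }
  for (col in names(sm$columns)) {
    cm <- sm$columns[[col]]
    term <- cm$term %||% cm
    if (!startsWith(term, "participant_")) next
    v <- col_value(row, col)
    if (is.na(v)) return(skip(paste0("missing participant column ", col)))
    uri <- switch(sub("participant_", "", term),
      chemical = {
        u <- compounds[[paste0("cid:", v)]]
        if (is.null(u) && grepl("^-?[0-9]+$", v)) u <- mint_uri("compound", v, base)
        u
      },
      protein = mint_uri("protein", toupper(v), base),
      drug = mint_uri("drug", v, base),
      side_effect = mint_uri("side_effect", v, base),
      disease = {
        d <- resolve_disease(v, ctx, quiet = quiet)
        if (is.null(d)) NULL else d$uri[[1]]
      }
    )
    if (is.null(uri)) return(skip(paste0("unresolvable participant '", v, "'")))
    participants[[term]] <- c(participants[[term]], uri)
  }
  if (length(participants) == 0) return(skip("no participants"))

  # disease_gene records are direct links, not interaction nodes
  if (sm$kind == "disease_gene") {
    return(triple_rows(participants$participant_disease,
                       puri("c2b2r:has_disease_gene"),
                       participants$participant_protein))
  }

  cls <- sm$class %||% NULL
  class_col <- cols_with_role(sm, "interaction_class")
  if (length(class_col) > 0) {
    v <- col_value(row, class_col[[1]])
    cls <- sm$columns[[class_col[[1]]]]$values[[v]] %||% NULL
    if (is.null(cls)) return(skip(paste0("unmapped interaction type '", v, "'")))
  }
  if (is.null(cls)) {
    cls <- switch(sm$kind,
      chemical_protein_interaction = "ChemicalProteinInteraction",
      drug_disease = , drug_side_effect = "DrugInducedSideEffect",
      drug_treatment = "DrugTreatment",
      protein_protein_interaction = "ProteinProteinInteraction",
      drug_drug_interaction = "DrugDrugInteraction"
    )
  }
  iuri <- mint_uri("interaction", paste0(src, "_", rec_id), base)
  allp <- unlist(participants, use.names = FALSE)
  tt <- list(
    triple_rows(iuri, RDF_TYPE, curi(cls)),
    triple_rows(iuri, ro_ns("has_participant"), allp),
    xref_node_rows(iuri, xref(src, rec_id), "UnificationXref", base, curi, puri)
  )

  desc_col <- cols_with_role(sm, "assay_description")
  out_cols <- list(
    measurement = cols_with_role(sm, "outcome_measurement"),
    relation = cols_with_role(sm, "outcome_relation"),
    value = cols_with_role(sm, "outcome_value"),
    unit = cols_with_role(sm, "outcome_unit")
  )
  has_assay <- length(desc_col) > 0 && !is.na(col_value(row, desc_col[[1]]))
  if (has_assay) {
    assay <- skolem_uri(base, "bioassay", iuri, col_value(row, desc_col[[1]]))
    tt <- c(tt, list(
      triple_rows(iuri, bp_ns("evidence"), assay),
      triple_rows(assay, RDF_TYPE, curi("BioAssay")),
      triple_rows(assay, puri("c2b2r:description"),
                  col_value(row, desc_col[[1]]), is_literal = TRUE,
                  datatype = xsd_ns("string"))
    ))
    vals <- lapply(out_cols, function(cc) {
      if (length(cc) > 0) col_value(row, cc[[1]]) else NA_character_
    })
    if (!is.na(vals$value)) {
      onode <- skolem_uri(base, "outcome", assay, vals$measurement,
                          vals$relation, vals$value, vals$unit)
      lit <- literal_num(vals$value)
      tt <- c(tt, list(
        triple_rows(assay, puri("c2b2r:hasOutcome"), onode),
        triple_rows(onode, RDF_TYPE, curi("BioAssayOutcome")),
        triple_rows(onode, puri("c2b2r:value"), lit$value, is_literal = TRUE,
                    datatype = lit$datatype)
      ))
      for (f in c("measurement", "relation", "unit")) {
        if (!is.na(vals[[f]])) {
          tt <- c(tt, list(triple_rows(onode, puri(paste0("c2b2r:", f)),
                                       vals[[f]], is_literal = TRUE,
                                       datatype = xsd_ns("string"))))
        }
      }
    }
    pub_col <- cols_with_role(sm, "publication")
    if (length(pub_col) > 0 && !is.na(col_value(row, pub_col[[1]]))) {
      pdb <- sm$columns[[pub_col[[1]]]]$db %||% "PubMed"
      pid <- col_value(row, pub_col[[1]])
      pnode <- skolem_uri(base, "xref", "PublicationXref", pdb, pid)
      tt <- c(tt, list(
        triple_rows(assay, bp_ns("xref"), pnode),
        triple_rows(pnode, RDF_TYPE, curi("PublicationXref")),
        triple_rows(pnode, puri("c2b2r:DB"), pdb, is_literal = TRUE,
                    datatype = xsd_ns("string")),
        triple_rows(pnode, puri("c2b2r:ID"), pid, is_literal = TRUE,
                    datatype = xsd_ns("string"))
      ))
      title_col <- cols_with_role(sm, "publication_title")
      if (length(title_col) > 0 && !is.na(col_value(row, title_col[[1]]))) {
        tt <- c(tt, list(triple_rows(pnode, puri("c2b2r:title"),
                                     col_value(row, title_col[[1]]),
                                     is_literal = TRUE,
                                     datatype = xsd_ns("string"))))
      }
    }
  }
  dplyr::bind_rows(tt)
}

#' Attach cross-reference provenance to an existing node
#'
#' Adds one UnificationXref or PublicationXref node per (DB, ID) pair, with
#' `DB`, `ID` and optional `comments` data properties, linked from the
#' entity by `bp:xref`. Duplicate pairs collapse to one node.
#'
#' @param graph A `semantic_graph`.
#' @param entity_uri URI of a node already present in the graph.
#' @param xrefs Cross-reference tibble (`db`, `id`, optional `comments`).
#' @param kind `"unification"` or `"publication"`.
#' @param schema Schema used for class URIs (default: fresh [build_schema()]).
#' @return The augmented `semantic_graph`.
#' @export
attach_provenance <- function(graph, entity_uri, xrefs,
                              kind = c("unification", "publication"),
                              schema = build_schema()) {
  kind <- match.arg(kind)
  known <- unique(c(graph$triples$subject,
                    graph$triples$object[!graph$triples$is_literal]))
  if (!entity_uri %in% known) {
    rlang::abort(paste0("Entity not in graph: ", entity_uri),
                 class = "scb_lookup_error")
  }
  if (is.null(xrefs) || nrow(xrefs) == 0) return(graph)
  cls <- if (kind == "unification") "UnificationXref" else "PublicationXref"
  base <- unname(graph$namespaces[["c2b2r"]])
  tt <- xref_node_rows(entity_uri, tibble::as_tibble(xrefs), cls, base,
                       curi = function(x) class_uri(schema, x),
                       puri = function(p) expand_curie(p, graph$namespaces))
  graph_add(graph, tt)
}
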