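# Shipped query templates: the integrative query patterns of the toolkit,
# parameterized over labels, classes and thresholds. Each template expands
# to syntactically valid SPARQL within the supported subset.

sparql_prefixes <- function(ns = default_namespaces()) {
  paste0("PREFIX ", names(ns), ": <", unname(ns), ">", collapse = "\n")
}

sparql_escape_literal <- function(x) ttl_escape(as.character(x))

#' Expand a named query template
#'
#' Available templates:
#' * `drug_targets` (param `label`): proteins participating in any
#'   chemical-protein interaction with the labeled chemical.
#' * `drug_targets_by_source` (params `label`, `source`): the same, but
#'   restricted to interactions whose provenance names one source.
#' * `interaction_evidence` (params `chemical_label`, `protein_label`):
#'   assay descriptions, outcome quadruples and optional article titles.
#' * `ligands_by_activity` (params `protein_label`, `activity_class`,
#'   `max_weight`): compounds in an interaction of the given class with the
#'   protein, molecular weight strictly below the cutoff, with canonical
#'   SMILES when present.
#' * `disease_genes` / `disease_genes_expanded` (param `disease_uri`):
#'   genes of a disease, optionally unioned over its sub-diseases.
#' * `rank_targets` (param `disease_uri`): targets of disease-linked drugs
#'   with shared-drug counts (grouped, counted).
#'
#' @param name Template name.
#' @param ... Template parameters (see above).
#' @param ns Namespace table used for the PREFIX header.
#' @return SPARQL text.
#' @export
sparql_template <- function(name, ..., ns = default_namespaces()) {
  p <- list(...)
  hdr <- sparql_prefixes(ns)
  q <- switch(name,
    drug_targets = sprintf('
SELECT DISTINCT ?target_name
WHERE {
  ?chemical rdfs:label "%s" ;
            ro:participates_in ?interaction .
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?target .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label ?target_name .
}', sparql_escape_literal(p$label)),
    drug_targets_by_source = sprintf('
SELECT DISTINCT ?target_name
WHERE {
  ?chemical rdfs:label "%s" ;
            ro:participates_in ?interaction .
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?target ;
               bp:xref [ rdf:type c2b2r:UnificationXref ; c2b2r:DB "%s" ] .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label ?target_name .
}', sparql_escape_literal(p$label), sparql_escape_literal(p$source)),
    interaction_evidence = sprintf('
SELECT DISTINCT ?bioAssay ?description ?measurement ?relation ?value ?unit ?title
WHERE {
  ?chemical rdfs:label "%s" ;
            ro:participates_in ?interaction .
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?target ;
               bp:evidence ?bioAssay .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label "%s" .
  ?bioAssay rdf:type c2b2r:BioAssay ;
            c2b2r:description ?description ;
            c2b2r:hasOutcome [ c2b2r:measurement ?measurement ;
                               c2b2r:relation ?relation ;
                               c2b2r:value ?value ;
                               c2b2r:unit ?unit ] .
  OPTIONAL { ?bioAssay bp:xref [ rdf:type c2b2r:PublicationXref ;
                                 c2b2r:title ?title ] }
}
ORDER BY ?description',
      sparql_escape_literal(p$chemical_label),
      sparql_escape_literal(p$protein_label)),
    ligands_by_activity = sprintf('
SELECT DISTINCT ?chemical ?structureData
WHERE {
  ?interaction rdf:type c2b2r:%s ;
               ro:has_participant ?chemical ;
               ro:has_participant ?target .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label "%s" .
  ?chemical rdf:type c2b2r:SmallMolecule ;
            c2b2r:hasPhysicalProperty [ c2b2r:molecularWeight ?weight ] .
  OPTIONAL { ?chemical bp:structure [ bp:structureFormat "openeye_can_smiles" ;
                                      bp:structureData ?structureData ] }
  FILTER ( ?weight < %s )
}',
      p$activity_class, sparql_escape_literal(p$protein_label),
      format(p$max_weight, scientific = FALSE)),
    drug_target_pairs = '
SELECT DISTINCT ?chem_label ?target_name
WHERE {
  ?chemical rdfs:label ?chem_label ;
            ro:participates_in ?interaction .
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?target .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label ?target_name .
}',
    drug_target_pairs_by_source = sprintf('
SELECT DISTINCT ?chem_label ?target_name
WHERE {
  ?chemical rdfs:label ?chem_label ;
            ro:participates_in ?interaction .
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?target ;
               bp:xref [ rdf:type c2b2r:UnificationXref ; c2b2r:DB "%s" ] .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label ?target_name .
}', sparql_escape_literal(p$source)),
    disease_genes = sprintf('
SELECT DISTINCT ?gene
WHERE {
  <%s> c2b2r:has_disease_gene ?gene .
}', p$disease_uri),
    disease_genes_expanded = sprintf('
SELECT DISTINCT ?gene
WHERE {
  { <%s> c2b2r:has_disease_gene ?gene . }
  UNION
  { ?sub c2b2r:subDiseaseOf <%s> .
    ?sub c2b2r:has_disease_gene ?gene . }
}', p$disease_uri, p$disease_uri),
    rank_targets = sprintf('
SELECT ?target_name (COUNT(DISTINCT ?drug) AS ?n)
WHERE {
  ?se rdf:type c2b2r:DrugInducedSideEffect ;
      ro:has_participant ?drug .
  ?drug rdf:type c2b2r:Drug .
  { ?se ro:has_participant <%s> . }
  UNION
  { ?se ro:has_participant ?dis .
    ?dis c2b2r:subDiseaseOf <%s> . }
  ?interaction rdf:type c2b2r:ChemicalProteinInteraction ;
               ro:has_participant ?drug ;
               ro:has_participant ?target .
  ?target rdf:type c2b2r:Protein ;
          rdfs:label ?target_name .
}
GROUP BY ?target_name', p$disease_uri, p$disease_uri),
    rlang::abort(paste0("Unknown query template: ", name),
                 class = "scb_lookup_error")
  )
  paste0(hdr, "\n", q, "\n")
}

#' Targets of a labeled chemical or drug
#'
#' All proteins participating in any chemical-protein interaction (any
#' subclass, seen through materialized typing) with the labeled chemical.
#'
#' @param graph A materialized `semantic_graph`.
#' @param drug_label Chemical or drug label.
#' @param source Optional source name; restricts to interactions whose
#'   provenance cross-reference names that source.
#' @return Tibble with column `target` (protein labels, sorted).
#' @export
drug_targets <- function(graph, drug_label, source = NULL) {
  q <- if (is.null(source)) {
    sparql_template("drug_targets", label = drug_label, ns = graph$namespaces)
  } else {
    sparql_template("drug_targets_by_source", label = drug_label,
                    source = source, ns = graph$namespaces)
  }
  res <- run_sparql(graph, q)
  tibble::tibble(target = sort(unique(res$target_name)))
}

#' Assay evidence for a chemical-protein pair
#'
#' One row per evidence bioassay, with its outcome quadruple and the
#' article title when a publication cross-reference exists.
#'
#' @param graph A materialized `semantic_graph`.
#' @param chemical_label,protein_label Labels of the pair.
#' @return Tibble with columns `description`, `measurement`, `relation`,
#'   `value`, `unit`, `title` (NA when no publication).
#' @export
interaction_evidence <- function(graph, chemical_label, protein_label) {
  res <- run_sparql(graph, sparql_template(
    "interaction_evidence", chemical_label = chemical_label,
    protein_label = protein_label, ns = graph$namespaces))
  out <- res[, c("description", "measurement", "relation", "value", "unit", "title")]
  out$value <- suppressWarnings(as.numeric(out$value))
  out
}

#' Ligands of a protein by activity class, filtered by molecular weight
#'
#' @param graph A materialized `semantic_graph`.
#' @param protein_label Protein label (e.g. a UniProt entry name).
#' @param activity_class An interaction class below
#'   ChemicalProteinInteraction (e.g. `"ReceptorAgonistActivity"`).
#' @param max_weight Strict upper bound on molecular weight; compounds at
#'   or above it are excluded.
#' @param schema Schema used to validate `activity_class`.
#' @return Tibble with columns `compound` (URI) and `smiles` (canonical
#'   SMILES when present, else NA).
#' @export
ligands_by_activity <- function(graph, protein_label, activity_class,
                                max_weight, schema = build_schema()) {
  chem_classes <- c("ChemicalProteinInteraction",
                    descendants(schema, "ChemicalProteinInteraction"))
  if (!activity_class %in% chem_classes) {
    rlang::abort(paste0("Not a chemical-protein interaction class: ",
                        activity_class), class = "scb_lookup_error")
  }
  res <- run_sparql(graph, sparql_template(
    "ligands_by_activity", protein_label = protein_label,
    activity_class = activity_class, max_weight = max_weight,
    ns = graph$namespaces))
  tibble::tibble(compound = res$chemical, smiles = res$structureData) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$compound)
}

# locate a disease node URI by DOID or label
disease_node_uri <- function(graph, disease_term) {
  tt <- graph$triples
  doid_p <- expand_curie("c2b2r:DOID", graph$namespaces)
  hit <- tt$subject[tt$predicate == doid_p & tt$object == disease_term]
  if (length(hit) == 0) {
    dis_nodes <- tt$subject[tt$predicate == RDF_TYPE &
                              tt$object == expand_curie("c2b2r:Disease",
                                                        graph$namespaces)]
    hit <- tt$subject[tt$predicate == RDFS_LABEL & tt$object == disease_term &
                        tt$subject %in% dis_nodes]
  }
  if (length(hit) == 0) {
    rlang::abort(paste0("Disease term not in graph: ", disease_term),
                 class = "scb_lookup_error")
  }
  sort(unique(hit))[[1]]
}

#' Genes linked to a disease, optionally through its sub-diseases
#'
#' @param graph A materialized `semantic_graph` containing the disease
#'   hierarchy.
#' @param disease_term A Disease Ontology identifier or a disease label.
#' @param expand Include genes of all descendant diseases (default FALSE).
#' @return Tibble with column `gene` (protein URIs, sorted).
#' @export
disease_genes <- function(graph, disease_term, expand = FALSE) {
  uri <- disease_node_uri(graph, disease_term)
  tpl <- if (expand) "disease_genes_expanded" else "disease_genes"
  res <- run_sparql(graph, sparql_template(tpl, disease_uri = uri,
                                           ns = graph$namespaces))
  tibble::tibble(gene = sort(unique(res$gene)))
}

#' Rank targets of disease-linked drugs by shared drug count
#'
#' Finds the drugs linked to the disease (through drug-induced side-effect
#' interactions, including descendant diseases when `expand` is TRUE), then
#' every target of any such drug, counting for each target the distinct
#' disease-linked drugs hitting it. Sorted by descending count, ties broken
#' alphabetically by target label.
#'
#' @param graph A materialized `semantic_graph`.
#' @param disease_term A Disease Ontology identifier or disease label.
#' @param expand Include descendant diseases (default TRUE).
#' @return Tibble of class `scb_ranked_targets` with columns `target` and
#'   `shared_drug_count`.
#' @export
rank_targets_by_shared_drugs <- function(graph, disease_term, expand = TRUE) {
  uri <- disease_node_uri(graph, disease_term)
  res <- run_sparql(graph, sparql_template("rank_targets", disease_uri = uri,
                                           ns = graph$namespaces))
  if (!expand) {
    # re-run restricted: direct disease participation only
    q <- sparql_template("rank_targets", disease_uri = uri,
                         ns = graph$namespaces)
    # the template already unions direct and descendant links; for the
    # unexpanded variant drop the descendant branch
    q <- sub("UNION\\s*\\{[^}]*subDiseaseOf[^}]*\\}", "", q)
    res <- run_sparql(graph, q)
  }
  out <- tibble::tibble(target = res$target_name,
                        shared_drug_count = as.integer(res$n)) |>
    dplyr::arrange(dplyr::desc(.data$shared_drug_count), .data$target)
  class(out) <- c("scb_ranked_targets", class(out))
  out
}
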