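wx_graph <- function() {
  sc <- build_schema()
  materialize(annotate_worked_example(), sc)
}

test_that("the ontology-level drug-target query finds PPARG", {
  gm <- wx_graph()
  q <- sparql_template("drug_targets", label = "Troglitazone")
  expect_identical(run_sparql(gm, q)$target_name, "PPARG")
  # absent label -> empty bindings
  q2 <- sparql_template("drug_targets", label = "Nonexistine")
  expect_identical(nrow(run_sparql(gm, q2)), 0L)
})

test_that("a hand-written query with FILTER, UNION and OPTIONAL evaluates", {
  gm <- wx_graph()
  q <- paste0(scbgraph:::sparql_prefixes(), '
SELECT DISTINCT ?lbl ?cid ?title
WHERE {
  { ?c rdf:type c2b2r:SmallMolecule . }
  UNION
  { ?c rdf:type c2b2r:Protein . }
  ?c rdfs:label ?lbl .
  OPTIONAL { ?c c2b2r:CID ?cid . }
  OPTIONAL { ?c c2b2r:title ?title . }
  FILTER ( ?lbl != "nobody" )
}
ORDER BY ?lbl')
  res <- run_sparql(gm, q)
  expect_identical(res$lbl, c("PPARG", "Troglitazone"))
  expect_identical(res$cid, c(NA, "5591"))
  expect_true(all(is.na(res$title)))
})

test_that("numeric FILTER comparisons are strict and typed", {
  gm <- wx_graph()
  q <- function(op, v) paste0(scbgraph:::sparql_prefixes(), sprintf('
SELECT ?o WHERE { ?o c2b2r:value ?v . FILTER ( ?v %s %s ) }', op, v))
  expect_identical(nrow(run_sparql(gm, q("<", "200"))), 0L)
  expect_identical(nrow(run_sparql(gm, q("<", "200.5"))), 1L)
  expect_identical(nrow(run_sparql(gm, q("=", "200"))), 1L)
  expect_identical(nrow(run_sparql(gm, q(">", "199"))), 1L)
})

test_that("GROUP BY with COUNT DISTINCT aggregates correctly", {
  sh <- get_shared_fixture()
  gm <- sh$materialized
  q <- paste0(scbgraph:::sparql_prefixes(), '
SELECT ?target (COUNT(DISTINCT ?i) AS ?n)
WHERE {
  ?i rdf:type c2b2r:ChemicalProteinInteraction ;
     ro:has_participant ?target .
  ?target rdf:type c2b2r:Protein .
}
GROUP BY ?target')
  res <- run_sparql(gm, q)
  # brute-force recount from the raw triples
  tt <- gm$triples
  base <- scb_base_uri()
  prot <- tt$subject[tt$predicate == scbgraph:::RDF_TYPE &
                       tt$object == paste0(base, "Protein")]
  cpi <- tt$subject[tt$predicate == scbgraph:::RDF_TYPE &
                      tt$object == paste0(base, "ChemicalProteinInteraction")]
  hp <- tt[tt$predicate == scbgraph:::ro_ns("has_participant") &
             tt$subject %in% cpi & tt$object %in% prot, ]
  expected <- dplyr::count(dplyr::distinct(hp, .data$subject, .data$object),
                           .data$object)
  got <- stats::setNames(res$n, res$target)
  expect_identical(sort(names(got)), sort(expected$object))
  expect_identical(unname(got[expected$object]), as.integer(expected$n))
})

test_that("results are invariant to triple insertion order", {
  sh <- get_shared_fixture()
  gm <- sh$materialized
  shuffled <- withr::with_seed(99, {
    semantic_graph(gm$triples[sample(nrow(gm$triples)), ], gm$namespaces)
  })
  q <- sparql_template("drug_target_pairs")
  a <- dplyr::arrange(run_sparql(gm, q), .data$chem_label, .data$target_name)
  b <- dplyr::arrange(run_sparql(shuffled, q), .data$chem_label, .data$target_name)
  expect_identical(a, b)
})

test_that("syntax errors carry a position; unsupported features are typed", {
  g <- semantic_graph()
  expect_error(run_sparql(g, "SELECT ?x WHERE { ?x rdf:type }"),
               regexp = "position", class = "scb_parse_error")
  expect_error(run_sparql(g, "SELECT ?x FROM WHERE { }"),
               class = "scb_parse_error")
  expect_error(run_sparql(g, "ASK { ?s ?p ?o }"),
               class = "scb_unsupported_feature")
  expect_error(run_sparql(g, "SELECT ?x WHERE { BIND(1 AS ?x) }"),
               class = "scb_unsupported_feature")
  expect_error(run_sparql(g, "SELECT ?x WHERE { ?s ?p ?o } LIMIT 5"),
               class = "scb_unsupported_feature")
  expect_error(
    run_sparql(g, "SELECT ?x WHERE { ?x rdf:type ?y }"),
    regexp = "undeclared prefix", class = "scb_parse_error")
})

test_that("templates substitute into parseable SPARQL", {
  for (q in list(
    sparql_template("drug_targets", label = "x \"quoted\""),
    sparql_template("drug_targets_by_source", label = "x", source = "s"),
    sparql_template("interaction_evidence", chemical_label = "a",
                    protein_label = "b"),
    sparql_template("ligands_by_activity", protein_label = "p",
                    activity_class = "Binding", max_weight = 500),
    sparql_template("disease_genes", disease_uri = "urn:d"),
    sparql_template("disease_genes_expanded", disease_uri = "urn:d"),
    sparql_template("rank_targets", disease_uri = "urn:d"),
    sparql_template("drug_target_pairs"),
    sparql_template("drug_target_pairs_by_source", source = "s"))) {
    expect_silent(scbgraph:::parse_sparql(q))
  }
  expect_error(sparql_template("no_such"), class = "scb_lookup_error")
})
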