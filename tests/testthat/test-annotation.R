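minimal_compound_sources <- function() {
  list(pubchem = tibble::tibble(
    cid = 7L, name = "tiny", inchi = NA_character_, smiles = NA_character_,
    mw = NA_real_, chebi = NA_integer_))
}
minimal_mapping <- function() {
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources["pubchem"]
  mp
}

test_that("a minimal entity record yields exactly the hand-enumerated triples", {
  sc <- build_schema()
  g <- annotate(minimal_compound_sources(), minimal_mapping(), sc)
  tt <- g$triples
  base <- scb_base_uri()
  cmp <- paste0(base, "compound7")
  xnode <- tt$object[tt$subject == cmp &
                       tt$predicate == scbgraph:::bp_ns("xref")]
  expect_length(xnode, 1)
  oracle <- tibble::tibble(
    subject = c(cmp, cmp, cmp, cmp, xnode, xnode, xnode),
    predicate = c(scbgraph:::RDF_TYPE, scbgraph:::RDFS_LABEL,
                  paste0(base, "CID"), scbgraph:::bp_ns("xref"),
                  scbgraph:::RDF_TYPE, paste0(base, "DB"), paste0(base, "ID")),
    object = c(paste0(base, "SmallMolecule"), "tiny", "7", xnode,
               paste0(base, "UnificationXref"), "PubChem", "7"),
    is_literal = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  expect_setequal(
    paste(tt$subject, tt$predicate, tt$object, tt$is_literal),
    paste(oracle$subject, oracle$predicate, oracle$object, oracle$is_literal))
})

test_that("the worked example produces the expected interaction structure", {
  sc <- build_schema()
  g <- annotate_worked_example()
  tt <- g$triples
  base <- scb_base_uri()
  ints <- tt$subject[tt$predicate == scbgraph:::RDF_TYPE &
                       tt$object == paste0(base, "Binding")]
  expect_length(ints, 1)
  parts <- tt$object[tt$subject == ints &
                       tt$predicate == scbgraph:::ro_ns("has_participant")]
  expect_setequal(parts, c(paste0(base, "compound5591"),
                           paste0(base, "proteinPPARG")))
  assay <- tt$object[tt$subject == ints &
                       tt$predicate == scbgraph:::bp_ns("evidence")]
  expect_length(assay, 1)
  expect_true(paste0(base, "BioAssay") %in%
                tt$object[tt$subject == assay & tt$predicate == scbgraph:::RDF_TYPE])
  outc <- tt$object[tt$subject == assay & tt$predicate == paste0(base, "hasOutcome")]
  expect_length(outc, 1)
  ofields <- tt[tt$subject == outc & tt$is_literal, ]
  got <- stats::setNames(ofields$object, sub(".*#", "", ofields$predicate))
  expect_identical(unname(got[c("measurement", "relation", "value", "unit")]),
                   c("IC50", "=", "200", "nm"))
  # compound provenance: PubChem 5591 and ChEBI 9753
  xr <- tt$object[tt$subject == paste0(base, "compound5591") &
                    tt$predicate == scbgraph:::bp_ns("xref")]
  dbs <- tt$object[tt$subject %in% xr & tt$predicate == paste0(base, "DB")]
  ids <- tt$object[tt$subject %in% xr & tt$predicate == paste0(base, "ID")]
  expect_setequal(dbs, c("PubChem", "ChEBI"))
  expect_setequal(ids, c("5591", "9753"))
})

test_that("each instance gets exactly one asserted type", {
  sh <- get_shared_fixture()
  tt <- sh$graph$triples
  types <- tt[tt$predicate == scbgraph:::RDF_TYPE & tt$origin == "asserted", ]
  expect_identical(max(table(types$subject)), 1L)
})

test_that("parallel interaction records stay distinct; entities merge", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = TRUE)
  mp$sources <- mp$sources[c("pubchem", "uniprot", "bindingdb", "ctd")]
  compounds <- tibble::tibble(
    cid = 42L, name = "shared-compound", inchi = "InChI=1S/s42",
    smiles = "CC", mw = 200, chebi = 9000L)
  proteins <- tibble::tibble(entry = "TGT_HUMAN", protein_name = "target",
                             go_terms = "GO:0000001")
  bdb <- tibble::tibble(
    compound_cid = 42L, uniprot = "TGT_HUMAN", act_type = "binding",
    assay_desc = "a", measure = "Ki", rel = "=", val = 1, unit = "nm",
    pmid = NA_character_, article_title = NA_character_)
  ctd <- tibble::tibble(chem_cid = 42L, protein_acc = "TGT_HUMAN",
                        interaction = "binds")
  g <- annotate(list(pubchem = compounds, uniprot = proteins,
                     bindingdb = bdb, ctd = ctd), mp, sc)
  tt <- g$triples
  base <- scb_base_uri()
  ints <- unique(tt$subject[tt$predicate == scbgraph:::ro_ns("has_participant")])
  expect_length(ints, 2)  # one per source record, sharing both participants
  for (i in ints) {
    expect_setequal(
      tt$object[tt$subject == i &
                  tt$predicate == scbgraph:::ro_ns("has_participant")],
      c(paste0(base, "compound42"), paste0(base, "proteinTGT_HUMAN")))
  }
  # every interaction node carries provenance naming its source
  for (i in ints) {
    xr <- tt$object[tt$subject == i & tt$predicate == scbgraph:::bp_ns("xref")]
    dbs <- tt$object[tt$subject %in% xr &
                       tt$predicate == paste0(base, "DB")]
    expect_length(dbs, 1)
    expect_true(dbs %in% c("bindingdb", "ctd"))
  }
})

test_that("annotation is idempotent under deduplication and re-annotation", {
  sc <- build_schema()
  src <- minimal_compound_sources()
  g1 <- annotate(src, minimal_mapping(), sc)
  g2 <- deduplicate(graph_add(g1, g1$triples))
  expect_true(graph_isomorphic(g1, g2))
  g3 <- annotate(src, minimal_mapping(), sc)
  expect_true(graph_isomorphic(g1, g3))
  expect_identical(nrow(annotate(list(), minimal_mapping(), sc)$triples), 0L)
})

test_that("compound records from different sources merge to one node", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("pubchem", "chembl")]
  pub <- tibble::tibble(cid = 9L, name = "merged", inchi = "InChI=1S/m9",
                        smiles = "C", mw = 100, chebi = 500L)
  che <- tibble::tibble(molregno = "CHEMBL9", pref_name = "merged",
                        std_inchi = "InChI=1S/m9", mol_weight = 100)
  ctx <- resolution_context(tibble::tibble(inchi = "InChI=1S/m9", cid = 9L))
  g <- annotate(list(pubchem = pub, chembl = che), mp, sc, ctx)
  tt <- g$triples
  base <- scb_base_uri()
  comp_nodes <- tt$subject[tt$predicate == scbgraph:::RDF_TYPE &
                             tt$object == paste0(base, "SmallMolecule")]
  expect_identical(unique(comp_nodes), paste0(base, "compound9"))
  # union of xrefs from both sources, verified against a brute-force union
  xr <- tt$object[tt$subject == paste0(base, "compound9") &
                    tt$predicate == scbgraph:::bp_ns("xref")]
  dbs <- sort(tt$object[tt$subject %in% xr & tt$predicate == paste0(base, "DB")])
  expect_identical(dbs, sort(c("PubChem", "ChEBI", "ChEMBL")))
})

test_that("attach_provenance adds collapsed xref nodes and validates the URI", {
  g <- annotate_worked_example()
  base <- scb_base_uri()
  cmp <- paste0(base, "compound5591")
  before <- nrow(g$triples)
  g2 <- attach_provenance(g, cmp, xref(c("KEGG", "KEGG"), c("C01", "C01")),
                          "unification")
  tt2 <- g2$triples
  kegg <- tt2$subject[tt2$predicate == paste0(base, "ID") & tt2$object == "C01"]
  expect_length(kegg, 1)
  expect_identical(attach_provenance(g, cmp, xref("A", "1")[0, ], "unification"),
                   g)
  expect_error(attach_provenance(g, paste0(base, "nope"), xref("A", "1")),
               class = "scb_lookup_error")
  # publication xrefs type as PublicationXref
  ints <- g$triples$subject[g$triples$predicate == scbgraph:::ro_ns("has_participant")]
  g3 <- attach_provenance(g, ints[[1]], xref("PubMed", "123"), "publication")
  expect_true(paste0(base, "PublicationXref") %in% g3$triples$object)
})

test_that("records with unresolvable participants are skipped with a reason", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("uniprot", "drugbank_drugs", "sider")]
  drugs <- tibble::tibble(dbid = "DB1", generic_name = "d1", cid = NA_integer_)
  prot <- tibble::tibble(entry = "P1_HUMAN", protein_name = "p",
                         go_terms = "GO:0000001")
  sider <- tibble::tibble(dbid = c("DB1", "DB1"),
                          disease_term = c("hepatitis", "no such malady xyz"))
  ctx <- resolution_context(do_terms = scbgraph:::fixed_disease_tree())
  expect_message(
    g <- annotate(list(uniprot = prot, drugbank_drugs = drugs, sider = sider),
                  mp, sc, ctx, quiet = FALSE),
    class = "scb_skipped_record")
  tt <- g$triples
  ints <- tt$subject[tt$predicate == scbgraph:::RDF_TYPE &
                       tt$object == paste0(scb_base_uri(), "DrugInducedSideEffect")]
  expect_length(ints, 1)
})

test_that("unparseable numeric outcomes are kept as text, not numbers", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("pubchem", "uniprot", "bindingdb")]
  pub <- tibble::tibble(cid = 3L, name = "c3", inchi = NA_character_,
                        smiles = NA_character_, mw = NA_real_,
                        chebi = NA_integer_)
  prot <- tibble::tibble(entry = "P3_HUMAN", protein_name = "p",
                         go_terms = NA_character_)
  bdb <- tibble::tibble(compound_cid = 3L, uniprot = "P3_HUMAN",
                        act_type = "binding", assay_desc = "a",
                        measure = "IC50", rel = "=", val = "not-a-number",
                        unit = "nm", pmid = NA_character_,
                        article_title = NA_character_)
  g <- annotate(list(pubchem = pub, uniprot = prot, bindingdb = bdb), mp, sc)
  tt <- g$triples
  vrow <- tt[tt$predicate == paste0(scb_base_uri(), "value"), ]
  expect_identical(vrow$object, "not-a-number")
  expect_identical(vrow$datatype, scbgraph:::xsd_ns("string"))
})
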