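test_that("drug target search sees leaf-typed interactions through reasoning", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = TRUE)
  mp$sources <- mp$sources[c("pubchem", "uniprot", "ctd")]
  pub <- tibble::tibble(cid = 11L, name = "leafy", inchi = NA_character_,
                        smiles = NA_character_, mw = 300,
                        chebi = NA_integer_)
  prot <- tibble::tibble(entry = "EXP_HUMAN", protein_name = "p",
                         go_terms = NA_character_)
  ctd <- tibble::tibble(chem_cid = 11L, protein_acc = "EXP_HUMAN",
                        interaction = "increases^expression")
  g <- annotate(list(pubchem = pub, uniprot = prot, ctd = ctd), mp, sc)
  gm <- materialize(g, sc)
  expect_identical(drug_targets(gm, "leafy")$target, "EXP_HUMAN")
  # without reasoning the generic query misses the leaf-typed interaction
  expect_identical(nrow(drug_targets(g, "leafy")), 0L)
  # a query pinned to the leaf class agrees with the generic one
  base <- scb_base_uri()
  q_leaf <- gsub("ChemicalProteinInteraction", "ExpressionIncrease",
                 sparql_template("drug_targets", label = "leafy"))
  expect_identical(run_sparql(gm, q_leaf)$target_name, "EXP_HUMAN")
  expect_identical(nrow(drug_targets(gm, "unknown-drug")), 0L)
})

test_that("the ontology-level query equals the union of per-source queries", {
  sh <- get_shared_fixture()
  gm <- sh$materialized
  fx <- sh$fx
  pairs_all <- run_sparql(gm, sparql_template("drug_target_pairs"))
  per_source <- lapply(c("bindingdb", "ctd", "drugbank_actions"), function(s) {
    run_sparql(gm, sparql_template("drug_target_pairs_by_source", source = s))
  })
  union_pairs <- dplyr::distinct(dplyr::bind_rows(per_source))
  expect_setequal(
    paste(pairs_all$chem_label, pairs_all$target_name),
    paste(union_pairs$chem_label, union_pairs$target_name))
  # per-label sets also match the brute-force manifest
  for (lab in names(fx$manifest$drug_targets)) {
    expect_identical(drug_targets(gm, lab)$target,
                     fx$manifest$drug_targets[[lab]], label = lab)
  }
  # a single-source query never exceeds the ontology-level one
  one <- run_sparql(gm, sparql_template("drug_target_pairs_by_source",
                                        source = "bindingdb"))
  expect_true(all(paste(one$chem_label, one$target_name) %in%
                    paste(pairs_all$chem_label, pairs_all$target_name)))
})

test_that("evidence rows match the fixture manifest, with OPTIONAL titles", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("pubchem", "uniprot", "bindingdb")]
  pub <- tibble::tibble(cid = 21L, name = "probe", inchi = NA_character_,
                        smiles = NA_character_, mw = 250, chebi = NA_integer_)
  prot <- tibble::tibble(entry = "EVD_HUMAN", protein_name = "p",
                         go_terms = NA_character_)
  bdb <- tibble::tibble(
    compound_cid = 21L, uniprot = "EVD_HUMAN", act_type = "binding",
    assay_desc = sprintf("assay %d", 1:3),
    measure = c("IC50", "Ki", "EC50"), rel = "=", val = c(10, 20, 30),
    unit = c("nm", "nm", "um"),
    pmid = c("1", "2", NA), article_title = c("t1", "t2", NA))
  gm <- materialize(annotate(list(pubchem = pub, uniprot = prot,
                                  bindingdb = bdb), mp, sc), sc)
  ev <- interaction_evidence(gm, "probe", "EVD_HUMAN")
  expect_identical(nrow(ev), 3L)
  expect_identical(sum(!is.na(ev$title)), 2L)
  expect_identical(ev$description, sprintf("assay %d", 1:3))
  expect_identical(ev$value, c(10, 20, 30))
  expect_identical(nrow(interaction_evidence(gm, "probe", "NOBODY")), 0L)
  # worked example: exactly one evidence row
  wx <- materialize(annotate_worked_example(), sc)
  expect_identical(nrow(interaction_evidence(wx, "Troglitazone", "PPARG")), 1L)
})

test_that("ligand search respects activity class and strict weight cutoff", {
  sc <- build_schema()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("pubchem", "uniprot", "bindingdb")]
  pub <- tibble::tibble(
    cid = c(31L, 32L, 33L), name = c("ag-450", "ag-550", "antag-300"),
    inchi = NA_character_, smiles = c("CCO", "CCC", "CCN"),
    mw = c(450, 550, 300), chebi = NA_integer_)
  prot <- tibble::tibble(entry = "NR1I2", protein_name = "pxr",
                         go_terms = NA_character_)
  bdb <- tibble::tibble(
    compound_cid = c(31L, 32L, 33L), uniprot = "NR1I2",
    act_type = c("agonism", "agonism", "antagonism"),
    assay_desc = sprintf("assay %d", 1:3), measure = "EC50", rel = "=",
    val = 1, unit = "um", pmid = NA_character_, article_title = NA_character_)
  gm <- materialize(annotate(list(pubchem = pub, uniprot = prot,
                                  bindingdb = bdb), mp, sc), sc)
  ag <- ligands_by_activity(gm, "NR1I2", "ReceptorAgonistActivity", 500)
  expect_identical(ag$compound, paste0(scb_base_uri(), "compound31"))
  expect_identical(ag$smiles, "CCO")
  # boundary: exactly 500 is excluded
  expect_identical(nrow(ligands_by_activity(gm, "NR1I2",
                                            "ReceptorAgonistActivity", 450)), 0L)
  an <- ligands_by_activity(gm, "NR1I2", "ReceptorAntagonistActivity", 500)
  expect_identical(an$compound, paste0(scb_base_uri(), "compound33"))
  expect_identical(nrow(ligands_by_activity(gm, "NR1I2", "Binding", 0)), 0L)
  expect_error(ligands_by_activity(gm, "NR1I2", "DrugTreatment", 500),
               class = "scb_lookup_error")
})

test_that("disease gene search honors hierarchy expansion", {
  sc <- build_schema()
  base <- scb_base_uri()
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("uniprot", "ctd_disease_genes")]
  prot <- tibble::tibble(entry = "LIV_HUMAN", protein_name = "p",
                         go_terms = NA_character_)
  dg <- tibble::tibble(doid = "DOID:2237", gene = "LIV_HUMAN")  # hepatitis only
  ctx <- resolution_context(do_terms = scbgraph:::fixed_disease_tree())
  gm <- materialize(annotate(list(uniprot = prot, ctd_disease_genes = dg),
                             mp, sc, ctx), sc)
  expanded <- disease_genes(gm, "hepatobiliary disease", expand = TRUE)
  expect_identical(expanded$gene, paste0(base, "proteinLIV_HUMAN"))
  expect_identical(nrow(disease_genes(gm, "hepatobiliary disease",
                                      expand = FALSE)), 0L)
  expect_identical(disease_genes(gm, "DOID:2237", expand = FALSE)$gene,
                   paste0(base, "proteinLIV_HUMAN"))
  expect_error(disease_genes(gm, "DOID:99999"), class = "scb_lookup_error")
})

test_that("expanded disease genes equal the brute-force descendant union", {
  sh <- get_shared_fixture()
  gm <- sh$materialized
  fx <- sh$fx
  base <- scb_base_uri()
  for (d in fx$do_terms$doid) {
    got <- disease_genes(gm, d, expand = TRUE)$gene
    want <- paste0(base, "protein", fx$manifest$disease_genes_expanded[[d]],
                   recycle0 = TRUE)
    expect_setequal(got, want)
  }
})

test_that("target ranking equals brute-force bipartite counting on random fixtures", {
  sc <- build_schema()
  for (seed in 1:20) {
    rf <- random_ranking_fixture(seed)
    gm <- rank_fixture_graph(rf, sc)
    r <- rank_targets_by_shared_drugs(gm, "DOID:114")
    expect_identical(r$target, rf$expected$swissprot, label = paste("seed", seed))
    expect_identical(r$shared_drug_count, as.integer(rf$expected$n),
                     label = paste("seed", seed))
  }
})

test_that("ranking orders by count then label, and handles empty cases", {
  sc <- build_schema()
  rf <- list(
    drugs = tibble::tibble(dbid = c("DB1", "DB2", "DB3"),
                           generic_name = c("d1", "d2", "d3"),
                           cid = NA_integer_),
    proteins = tibble::tibble(entry = c("T1_HUMAN", "T2_HUMAN"),
                              protein_name = "p", go_terms = NA_character_),
    sider = tibble::tibble(dbid = c("DB1", "DB2", "DB3"),
                           disease_term = "heart disease"),
    actions = tibble::tibble(dbid = c("DB1", "DB2", "DB3"),
                             swissprot = c("T1_HUMAN", "T1_HUMAN", "T2_HUMAN"),
                             action = "binder"))
  gm <- rank_fixture_graph(rf, sc)
  r <- rank_targets_by_shared_drugs(gm, "DOID:114")
  expect_identical(r$target, c("T1_HUMAN", "T2_HUMAN"))
  expect_identical(r$shared_drug_count, c(2L, 1L))
  # no disease-linked drugs -> empty ranking
  r2 <- rank_targets_by_shared_drugs(gm, "DOID:2044")
  expect_identical(nrow(r2), 0L)
})
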