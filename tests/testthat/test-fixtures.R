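test_that("fixture generation is deterministic and byte-identical", {
  cfg <- fixture_config(seed = 11, n_compounds = 25, n_drugs = 6,
                        n_proteins = 8, n_interactions = 30,
                        n_side_effects = 10)
  fx1 <- generate_fixtures(cfg)
  fx2 <- generate_fixtures(cfg)
  expect_identical(fx1$sources, fx2$sources)
  expect_identical(fx1$manifest, fx2$manifest)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_fixtures(fx1, d1)
  write_fixtures(fx2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("configured counts are honored in the emitted tables", {
  cfg <- fixture_config(seed = 12, n_compounds = 25, n_drugs = 6,
                        n_proteins = 8, n_interactions = 30,
                        n_diseases = 11, n_side_effects = 10)
  fx <- generate_fixtures(cfg)
  expect_identical(nrow(fx$sources$pubchem), 25L)
  expect_identical(nrow(fx$sources$drugbank_drugs), 6L)
  expect_identical(nrow(fx$sources$uniprot), 8L)
  expect_identical(nrow(fx$sources$bindingdb) + nrow(fx$sources$ctd) +
                     nrow(fx$sources$drugbank_actions), 30L)
  expect_identical(nrow(fx$do_terms), 11L)
  expect_identical(nrow(fx$sources$sider), 10L)
  expect_error(fixture_config(n_compounds = -1), class = "scb_validation_error")
  expect_error(fixture_config(n_diseases = 3), class = "scb_validation_error")
})

test_that("interaction sources use different column vocabularies", {
  fx <- get_shared_fixture()$fx
  expect_false(any(names(fx$sources$bindingdb) %in% names(fx$sources$ctd)))
  expect_true(all(c("compound_cid", "uniprot") %in% names(fx$sources$bindingdb)))
  expect_true(all(c("chem_cid", "protein_acc") %in% names(fx$sources$ctd)))
})

test_that("cross-source compound overlap guarantees merge cases", {
  fx <- get_shared_fixture()$fx
  overlap <- intersect(fx$sources$chembl$std_inchi, fx$sources$pubchem$inchi)
  expect_gt(length(overlap), 0)
  orphans <- setdiff(fx$sources$chembl$std_inchi, fx$lookup$inchi)
  expect_gt(length(orphans), 0)  # surrogate cases present
})

test_that("manifest drug-target sets equal independent recomputation", {
  fx <- get_shared_fixture()$fx
  # recompute with a second, plain-loop pass over the emitted tables
  cid2label <- stats::setNames(fx$sources$pubchem$name,
                               as.character(fx$sources$pubchem$cid))
  db2label <- stats::setNames(fx$sources$drugbank_drugs$generic_name,
                              fx$sources$drugbank_drugs$dbid)
  acc <- list()
  for (r in seq_len(nrow(fx$sources$bindingdb))) {
    lab <- cid2label[[as.character(fx$sources$bindingdb$compound_cid[[r]])]]
    acc[[lab]] <- c(acc[[lab]], fx$sources$bindingdb$uniprot[[r]])
  }
  for (r in seq_len(nrow(fx$sources$ctd))) {
    lab <- cid2label[[as.character(fx$sources$ctd$chem_cid[[r]])]]
    acc[[lab]] <- c(acc[[lab]], fx$sources$ctd$protein_acc[[r]])
  }
  for (r in seq_len(nrow(fx$sources$drugbank_actions))) {
    lab <- db2label[[fx$sources$drugbank_actions$dbid[[r]]]]
    acc[[lab]] <- c(acc[[lab]], fx$sources$drugbank_actions$swissprot[[r]])
  }
  acc <- lapply(acc, function(x) sort(unique(x)))
  expect_identical(fx$manifest$drug_targets[sort(names(acc))],
                   acc[sort(names(acc))])
})

test_that("the worked example emits the printed cross-references", {
  wx <- worked_example()
  expect_identical(wx$sources$pubchem$cid, 5591L)
  expect_identical(wx$sources$pubchem$chebi, 9753L)
  expect_identical(wx$sources$pubchem$name, "Troglitazone")
  expect_identical(wx$sources$uniprot$entry, "PPARG")
  sc <- build_schema()
  gm <- materialize(annotate_worked_example(), sc)
  expect_identical(drug_targets(gm, "Troglitazone")$target, "PPARG")
})

test_that("mapping files round-trip through YAML and validate", {
  fx <- get_shared_fixture()$fx
  d <- withr::local_tempdir()
  write_fixtures(fx, d)
  m <- read_mapping(file.path(d, "mapping.yaml"))
  sc <- build_schema()
  expect_silent(validate_mapping(m, sc))
  expect_identical(names(m$sources), names(fx$mapping$sources))
  bad <- fx$mapping
  bad$sources$pubchem$columns$name$term <- "c2b2r:noSuchProperty"
  expect_error(validate_mapping(bad, sc), class = "scb_config_error")
  bad2 <- fx$mapping
  bad2$sources$bindingdb$columns$act_type$values$binding <- "NoSuchClass"
  expect_error(validate_mapping(bad2, sc), class = "scb_config_error")
})
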