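# Deterministic synthetic source tables emulating the shape (not the scale
# or chemistry) of public chemogenomics databases: a PubChem-like compound
# hub, a ChEMBL-like compound table without CIDs, UniProt-like proteins,
# DrugBank-like drugs and drug-target actions, BindingDB-like assayed
# interactions, a CTD-like interaction and disease-gene table, a SIDER-like
# drug-side-effect table and a mini Disease Ontology tree with synonyms.
# A ground-truth manifest is recomputed from the emitted tables by brute
# force so every downstream module is testable without downloads.

#' Fixture generator configuration
#'
#' @param seed Integer seed; the same configuration always yields
#'   byte-identical outputs.
#' @param n_compounds Rows in the PubChem-like hub table.
#' @param n_drugs,n_proteins,n_interactions,n_diseases,n_side_effects
#'   Row counts for the corresponding tables (`n_interactions` is split
#'   across the interaction sources; `n_side_effects` is the number of
#'   drug-disease link records).
#' @param n_sources Number of chemical-protein interaction sources (1 or 2).
#' @param surrogate_fraction Fraction of extra compounds that lack both a
#'   CID and a lookup entry, exercising surrogate minting.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 42L, n_compounds = 200L, n_drugs = 30L,
                           n_proteins = 40L, n_interactions = 150L,
                           n_sources = 2L, n_diseases = 12L,
                           n_side_effects = 40L, surrogate_fraction = 0.1) {
  cfg <- list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
              n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
              n_interactions = as.integer(n_interactions),
              n_sources = as.integer(n_sources),
              n_diseases = as.integer(n_diseases),
              n_side_effects = as.integer(n_side_effects),
              surrogate_fraction = surrogate_fraction)
  counts <- unlist(cfg[startsWith(names(cfg), "n_")])
  if (any(counts < 0) || surrogate_fraction < 0 || surrogate_fraction > 1 ||
      !cfg$n_sources %in% c(1L, 2L)) {
    rlang::abort("Invalid fixture configuration", class = "scb_validation_error")
  }
  if (cfg$n_diseases < 9L) {
    rlang::abort("n_diseases must be at least 9 (the fixed disease subtree)",
                 class = "scb_validation_error")
  }
  structure(cfg, class = c("fixture_config", "list"))
}

fixed_disease_tree <- function() {
  tibble::tribble(
    ~doid, ~label, ~synonyms, ~parent_doid,
    "DOID:4", "disease", "", "",
    "DOID:2044", "hepatobiliary disease", "liver toxicity|liver disease", "DOID:4",
    "DOID:2237", "hepatitis", "inflammation of liver", "DOID:2044",
    "DOID:13580", "cholestasis", "bile flow obstruction", "DOID:2044",
    "DOID:5082", "hepatorenal syndrome", "", "DOID:2044",
    "DOID:114", "heart disease", "heart attack|cardiac disease", "DOID:4",
    "DOID:6000", "heart failure", "congestive heart failure", "DOID:114",
    "DOID:10314", "endocarditis", "", "DOID:114",
    "DOID:1787", "pericarditis", "", "DOID:114"
  )
}

#' Generate a synthetic fixture set
#'
#' @param config A [fixture_config()].
#' @return List with `config`, `sources` (named list of tibbles),
#'   `lookup` (InChI to CID), `do_terms`, `similarity` pairs, `mapping`
#'   (column mapping list) and `manifest` (brute-force ground truth).
#' @export
generate_fixtures <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, generate_fixtures_impl(config))
}

generate_fixtures_impl <- function(cfg) {
  nC <- cfg$n_compounds; nP <- cfg$n_proteins; nD <- cfg$n_drugs

  cid <- sort(sample(1000:999999, nC))
  pubchem <- tibble::tibble(
    cid = cid,
    name = sprintf("compound-%05d", seq_len(nC)),
    inchi = sprintf("InChI=1S/C%dH%dO%d/synth%06d",
                    5 + seq_len(nC) %% 20, 6 + seq_len(nC) %% 24,
                    1 + seq_len(nC) %% 5, cid),
    smiles = vapply(seq_len(nC), function(i) {
      paste0("C", strrep("C", i %% 6), "O", strrep("N", i %% 3))
    }, character(1)),
    mw = round(stats::runif(nC, 150, 700), 1),
    chebi = ifelse(seq_len(nC) %% 3 == 0, NA_integer_, 30000L + seq_len(nC))
  )
  lookup <- tibble::tibble(inchi = pubchem$inchi, cid = pubchem$cid)

  # ChEMBL-like table: no CIDs; 30% overlap the hub via InChI, plus
  # surrogate-only compounds whose InChI misses the lookup
  n_over <- max(1L, round(0.3 * nC))
  over_idx <- sort(sample(seq_len(nC), n_over))
  n_surr <- round(cfg$surrogate_fraction * nC)
  chembl <- tibble::tibble(
    molregno = sprintf("CHEMBL%06d", seq_len(n_over + n_surr)),
    pref_name = c(pubchem$name[over_idx], sprintf("orphan-%04d", seq_len(n_surr))),
    std_inchi = c(pubchem$inchi[over_idx],
                  sprintf("InChI=1S/C9H11NO2/orphan%04d", seq_len(n_surr))),
    mol_weight = c(pubchem$mw[over_idx], round(stats::runif(n_surr, 150, 700), 1))
  )

  proteins <- tibble::tibble(
    entry = sprintf("PR%03d_HUMAN", seq_len(nP)),
    protein_name = sprintf("synthetic protein %03d", seq_len(nP)),
    go_terms = vapply(seq_len(nP), function(i) {
      paste(sprintf("GO:%07d", sort(sample(1:15, 1 + i %% 3))), collapse = "|")
    }, character(1))
  )

  drugs <- tibble::tibble(
    dbid = sprintf("DB%05d", seq_len(nD)),
    generic_name = sprintf("drug-%03d", seq_len(nD)),
    cid = sample(pubchem$cid, nD, replace = nD > nC)
  )

  n_bind <- round(0.4 * cfg$n_interactions)
  n_ctd <- if (cfg$n_sources >= 2L) round(0.4 * cfg$n_interactions) else 0L
  n_dbi <- cfg$n_interactions - n_bind - n_ctd

  bind_actions <- c("binding", "agonism", "antagonism", "inhibition")
  measures <- c("IC50", "EC50", "Ki", "Kd")
  bindingdb <- tibble::tibble(
    compound_cid = sample(pubchem$cid, n_bind, replace = TRUE),
    uniprot = sample(proteins$entry, n_bind, replace = TRUE),
    act_type = sample(bind_actions, n_bind, replace = TRUE),
    assay_desc = sprintf("synthetic displacement assay %04d", seq_len(n_bind)),
    measure = sample(measures, n_bind, replace = TRUE),
    rel = sample(c("=", "<", ">"), n_bind, replace = TRUE, prob = c(.7, .15, .15)),
    val = round(stats::runif(n_bind, 1, 5000), 1),
    unit = sample(c("um", "nm"), n_bind, replace = TRUE),
    pmid = ifelse(stats::runif(n_bind) < 0.6,
                  sprintf("%08d", sample(1e7, n_bind)), NA_character_),
    article_title = NA_character_
  )
  bindingdb$article_title <- ifelse(
    is.na(bindingdb$pmid), NA_character_,
    sprintf("synthetic article %s", bindingdb$pmid))

  ctd_vocab <- c("binds", "increases^expression", "decreases^expression",
                 "increases^phosphorylation", "affects^activity")
  ctd <- tibble::tibble(
    chem_cid = sample(pubchem$cid, n_ctd, replace = TRUE),
    protein_acc = sample(proteins$entry, n_ctd, replace = TRUE),
    interaction = sample(ctd_vocab, n_ctd, replace = TRUE)
  )

  dbi_vocab <- c("inhibitor", "agonist", "antagonist", "binder", "substrate")
  drugbank_actions <- tibble::tibble(
    dbid = sample(drugs$dbid, n_dbi, replace = TRUE),
    swissprot = sample(proteins$entry, n_dbi, replace = TRUE),
    action = sample(dbi_vocab, n_dbi, replace = TRUE)
  )

  do_terms <- fixed_disease_tree()
  n_extra <- cfg$n_diseases - nrow(do_terms)
  if (n_extra > 0) {
    do_terms <- dplyr::bind_rows(do_terms, tibble::tibble(
      doid = sprintf("DOID:9%04d", seq_len(n_extra)),
      label = sprintf("synthetic disease %03d", seq_len(n_extra)),
      synonyms = "",
      parent_doid = "DOID:4"
    ))
  }

  # free-text disease mentions drawn from labels and synonyms
  mention_pool <- unlist(lapply(seq_len(nrow(do_terms)), function(i) {
    syn <- strsplit(do_terms$synonyms[[i]], "|", fixed = TRUE)[[1]]
    c(do_terms$label[[i]], syn[nzchar(syn)])
  }))
  mention_pool <- setdiff(mention_pool, "disease")
  sider <- tibble::tibble(
    dbid = sample(drugs$dbid, cfg$n_side_effects, replace = TRUE),
    disease_term = sample(mention_pool, cfg$n_side_effects, replace = TRUE)
  )

  n_dg <- max(10L, 2L * cfg$n_diseases)
  disease_genes_tbl <- tibble::tibble(
    doid = sample(setdiff(do_terms$doid, "DOID:4"), n_dg, replace = TRUE),
    gene = sample(proteins$entry, n_dg, replace = TRUE)
  ) |> dplyr::distinct()

  n_sim <- min(40L, nC * (nC - 1L) / 2L)
  sim_pairs <- tibble::tibble(
    cid_a = sample(pubchem$cid, n_sim, replace = TRUE),
    cid_b = sample(pubchem$cid, n_sim, replace = TRUE),
    score = round(stats::runif(n_sim), 3)
  ) |> dplyr::filter(.data$cid_a != .data$cid_b)

  sources <- list(
    pubchem = pubchem, chembl = chembl, uniprot = proteins,
    drugbank_drugs = drugs, bindingdb = bindingdb,
    drugbank_actions = drugbank_actions, sider = sider,
    ctd_disease_genes = disease_genes_tbl
  )
  if (cfg$n_sources >= 2L) sources$ctd <- ctd

  fx <- list(config = cfg, sources = sources, lookup = lookup,
             do_terms = do_terms, similarity = sim_pairs,
             mapping = default_mapping(include_ctd = cfg$n_sources >= 2L))
  fx$manifest <- fixture_manifest(fx)
  fx
}

#' Column mapping for the synthetic fixture sources
#'
#' @param include_ctd Include the CTD-like interaction source.
#' @return Mapping list suitable for [annotate()] and [validate_mapping()].
#' @export
default_mapping <- function(include_ctd = TRUE) {
  m <- list(sources = list(
    pubchem = list(kind = "compound", id_column = "cid", columns = list(
      cid = list(term = "xref", db = "PubChem"),
      name = list(term = "label"),
      inchi = list(term = "inchi"),
      smiles = list(term = "structure", format = "openeye_can_smiles"),
      mw = list(term = "c2b2r:molecularWeight"),
      chebi = list(term = "xref", db = "ChEBI")
    )),
    chembl = list(kind = "compound", id_column = "molregno", columns = list(
      molregno = list(term = "xref", db = "ChEMBL"),
      pref_name = list(term = "label"),
      std_inchi = list(term = "inchi"),
      mol_weight = list(term = "c2b2r:molecularWeight")
    )),
    uniprot = list(kind = "protein", id_column = "entry", columns = list(
      entry = list(term = "label"),
      protein_name = list(term = "c2b2r:comments"),
      go_terms = list(term = "go_terms")
    )),
    drugbank_drugs = list(kind = "drug", id_column = "dbid", columns = list(
      dbid = list(term = "xref", db = "DrugBank"),
      generic_name = list(term = "label"),
      cid = list(term = "xref", db = "PubChem")
    )),
    bindingdb = list(kind = "chemical_protein_interaction", columns = list(
      compound_cid = list(term = "participant_chemical"),
      uniprot = list(term = "participant_protein"),
      act_type = list(term = "interaction_class", values = list(
        binding = "Binding", agonism = "ReceptorAgonistActivity",
        antagonism = "ReceptorAntagonistActivity", inhibition = "Inhibition")),
      assay_desc = list(term = "assay_description"),
      measure = list(term = "outcome_measurement"),
      rel = list(term = "outcome_relation"),
      val = list(term = "outcome_value"),
      unit = list(term = "outcome_unit"),
      pmid = list(term = "publication", db = "PubMed"),
      article_title = list(term = "publication_title")
    )),
    drugbank_actions = list(kind = "chemical_protein_interaction", columns = list(
      dbid = list(term = "participant_drug"),
      swissprot = list(term = "participant_protein"),
      action = list(term = "interaction_class", values = list(
        inhibitor = "Inhibition", agonist = "ReceptorAgonistActivity",
        antagonist = "ReceptorAntagonistActivity", binder = "Binding",
        substrate = "ChemicalMetabolism"))
    )),
    sider = list(kind = "drug_disease", columns = list(
      dbid = list(term = "participant_drug"),
      disease_term = list(term = "participant_disease")
    )),
    ctd_disease_genes = list(kind = "disease_gene", columns = list(
      doid = list(term = "participant_disease"),
      gene = list(term = "participant_protein")
    ))
  ))
  if (include_ctd) {
    m$sources$ctd <- list(kind = "chemical_protein_interaction", columns = list(
      chem_cid = list(term = "participant_chemical"),
      protein_acc = list(term = "participant_protein"),
      interaction = list(term = "interaction_class", values = list(
        binds = "Binding", `increases^expression` = "ExpressionIncrease",
        `decreases^expression` = "ExpressionDecrease",
        `increases^phosphorylation` = "PhosphorylationIncrease",
        `affects^activity` = "ActivityRegulation"))
    ))
  }
  m
}

# Brute-force ground truth recomputed from the emitted tables alone.
fixture_manifest <- function(fx) {
  src <- fx$sources
  cid_label <- stats::setNames(src$pubchem$name, as.character(src$pubchem$cid))
  per_source <- list()
  cpi <- list()
  if (!is.null(src$bindingdb) && nrow(src$bindingdb) > 0) {
    cpi$bindingdb <- tibble::tibble(
      label = unname(cid_label[as.character(src$bindingdb$compound_cid)]),
      target = src$bindingdb$uniprot)
  }
  if (!is.null(src$ctd) && nrow(src$ctd) > 0) {
    cpi$ctd <- tibble::tibble(
      label = unname(cid_label[as.character(src$ctd$chem_cid)]),
      target = src$ctd$protein_acc)
  }
  drug_label <- stats::setNames(src$drugbank_drugs$generic_name,
                                src$drugbank_drugs$dbid)
  if (!is.null(src$drugbank_actions) && nrow(src$drugbank_actions) > 0) {
    cpi$drugbank_actions <- tibble::tibble(
      label = unname(drug_label[src$drugbank_actions$dbid]),
      target = src$drugbank_actions$swissprot)
  }
  all_cpi <- dplyr::bind_rows(cpi, .id = "source")
  drug_targets <- split(all_cpi$target, all_cpi$label) |> lapply(\(x) sort(unique(x)))
  per_source <- lapply(cpi, function(df) {
    split(df$target, df$label) |> lapply(\(x) sort(unique(x)))
  })

  ev <- src$bindingdb |>
    dplyr::mutate(label = unname(cid_label[as.character(.data$compound_cid)])) |>
    dplyr::count(.data$label, .data$uniprot)
  evidence_counts <- stats::setNames(as.list(ev$n),
                                     paste(ev$label, ev$uniprot, sep = "|"))

  # disease descendants by brute-force DFS over the parent column
  dt <- fx$do_terms
  desc_of <- function(d) {
    out <- character(); frontier <- d
    while (length(frontier) > 0) {
      kids <- dt$doid[dt$parent_doid %in% frontier]
      kids <- setdiff(kids, out)
      out <- c(out, kids); frontier <- kids
    }
    out
  }
  dg <- src$ctd_disease_genes
  disease_genes_direct <- split(dg$gene, dg$doid) |> lapply(\(x) sort(unique(x)))
  disease_genes_expanded <- stats::setNames(lapply(dt$doid, function(d) {
    fam <- c(d, desc_of(d))
    sort(unique(dg$gene[dg$doid %in% fam]))
  }), dt$doid)

  # disease term resolution used by the SIDER-like table is exact-match
  term_to_doid <- local({
    keys <- character(); vals <- character()
    for (i in seq_len(nrow(dt))) {
      syn <- strsplit(dt$synonyms[[i]], "|", fixed = TRUE)[[1]]
      terms <- c(dt$label[[i]], syn[nzchar(syn)])
      keys <- c(keys, terms); vals <- c(vals, rep(dt$doid[[i]], length(terms)))
    }
    stats::setNames(vals, keys)
  })
  sider <- src$sider |>
    dplyr::mutate(doid = unname(term_to_doid[.data$disease_term]))
  ranking <- stats::setNames(lapply(dt$doid, function(d) {
    fam <- c(d, desc_of(d))
    dlinked <- unique(sider$dbid[sider$doid %in% fam])
    hits <- src$drugbank_actions[src$drugbank_actions$dbid %in% dlinked, ]
    if (nrow(hits) == 0) return(list())
    cnt <- hits |>
      dplyr::distinct(.data$dbid, .data$swissprot) |>
      dplyr::count(.data$swissprot, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$swissprot)
    stats::setNames(as.list(cnt$n), cnt$swissprot)
  }), dt$doid)

  list(drug_targets = drug_targets, drug_targets_by_source = per_source,
       evidence_counts = evidence_counts,
       disease_genes_direct = disease_genes_direct,
       disease_genes_expanded = disease_genes_expanded,
       ranking = ranking)
}

#' Write fixture tables to a directory
#'
#' Emits one TSV per source, `inchi_cid.tsv`, `do_terms.tsv`,
#' `similarity.tsv`, `mapping.yaml` and `manifest.json`. Output is
#' byte-identical for identical configurations.
#'
#' @param fx Result of [generate_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fx$sources)) {
    readr::write_tsv(fx$sources[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(fx$lookup, file.path(dir, "inchi_cid.tsv"), progress = FALSE)
  readr::write_tsv(fx$do_terms, file.path(dir, "do_terms.tsv"), progress = FALSE)
  readr::write_tsv(fx$similarity, file.path(dir, "similarity.tsv"),
                   progress = FALSE)
  yaml::write_yaml(fx$mapping, file.path(dir, "mapping.yaml"))
  jsonlite::write_json(fx$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' The Troglitazone-PPARG worked example
#'
#' A fixed micro-fixture: compound CID 5591 labeled Troglitazone with a
#' ChEBI cross-reference (9753), the PPARG receptor, and one binding
#' interaction backed by one bioassay with an outcome quadruple and a
#' publication reference. Assay outcome values are synthetic placeholders:
#' the scenario fixes the entities and their linkage, not real
#' measurements.
#'
#' @return List with `sources`, `mapping`, `lookup`, `do_terms`.
#' @export
worked_example <- function() {
  sources <- list(
    pubchem = tibble::tibble(
      cid = 5591L, name = "Troglitazone",
      inchi = "InChI=1S/C24H27NO5S/synthetic",
      smiles = "Cc1c(C)c2c(c(C)c1O)CCC(C)(COc1ccc(CC3SC(=O)NC3=O)cc1)O2",
      mw = 441.5, chebi = 9753L
    ),
    uniprot = tibble::tibble(
      entry = "PPARG", protein_name = "peroxisome proliferator-activated receptor gamma",
      go_terms = "GO:0003707|GO:0006355"
    ),
    bindingdb = tibble::tibble(
      compound_cid = 5591L, uniprot = "PPARG", act_type = "binding",
      assay_desc = "synthetic placeholder binding assay for Troglitazone against PPARG",
      measure = "IC50", rel = "=", val = 200, unit = "nm",
      pmid = "00000001",
      article_title = "synthetic placeholder article on thiazolidinedione binding"
    )
  )
  mapping <- default_mapping(include_ctd = FALSE)
  mapping$sources <- mapping$sources[c("pubchem", "uniprot", "bindingdb")]
  list(sources = sources, mapping = mapping,
       lookup = tibble::tibble(inchi = sources$pubchem$inchi, cid = 5591L),
       do_terms = fixed_disease_tree())
}

#' Annotate the worked example into a semantic graph
#'
#' @param materialized Materialize the graph before returning (default
#'   FALSE).
#' @return A `semantic_graph`.
#' @export
annotate_worked_example <- function(materialized = FALSE) {
  wx <- worked_example()
  sc <- build_schema()
  ctx <- resolution_context(wx$lookup, wx$do_terms)
  g <- annotate(wx$sources, wx$mapping, sc, ctx)
  if (materialized) materialize(g, sc) else g
}

#' A path-mining micro-fixture with three association motifs
#'
#' Builds a small materialized graph and entity graph around one query
#' compound and one target that are not directly linked, but are connected
#' by (i) structurally similar compounds binding the target, (ii) a second
#' target sharing ligands with it, and (iii) GO-term sharing between the
#' two targets.
#'
#' @return List with `graph` (materialized `semantic_graph`), `entity_graph`
#'   (similarity edges overlaid), `query_compound` and `target` URIs.
#' @export
path_mining_example <- function() {
  sc <- build_schema()
  compounds <- tibble::tibble(
    cid = c(44143441L, 44143442L, 44143438L, 44143439L, 77700001L),
    name = c("benzimidazole analogue", "analogue-2", "analogue-3",
             "analogue-4", "shared-ligand"),
    inchi = sprintf("InChI=1S/synthetic/path%02d", 1:5),
    smiles = c("c1ccc2[nH]cnc2c1", "Cc1ccc2[nH]cnc2c1", "CCc1ccc2[nH]cnc2c1",
               "Oc1ccc2[nH]cnc2c1", "CCN(CC)CC"),
    mw = c(320.4, 334.4, 348.5, 336.4, 101.2),
    chebi = NA_integer_
  )
  proteins <- tibble::tibble(
    entry = c("KCNH2", "OPRL1"),
    protein_name = c("hERG potassium channel", "opioid related nociceptin receptor"),
    go_terms = c("GO:0005244|GO:0005886", "GO:0004930|GO:0005886")
  )
  interactions <- tibble::tibble(
    compound_cid = c(44143442L, 44143438L, 44143439L,  # analogues bind hERG
                     44143441L,                         # query binds OPRL1
                     77700001L, 77700001L),             # shared ligand binds both
    uniprot = c("KCNH2", "KCNH2", "KCNH2", "OPRL1", "OPRL1", "KCNH2"),
    act_type = "binding",
    assay_desc = sprintf("synthetic binding assay %d", 1:6),
    measure = "Ki", rel = "=", val = c(12, 15, 20, 5, 40, 55), unit = "nm",
    pmid = NA_character_, article_title = NA_character_
  )
  mapping <- default_mapping(include_ctd = FALSE)
  mapping$sources <- mapping$sources[c("pubchem", "uniprot", "bindingdb")]
  ctx <- resolution_context(
    tibble::tibble(inchi = compounds$inchi, cid = compounds$cid))
  g <- annotate(list(pubchem = compounds, uniprot = proteins,
                     bindingdb = interactions), mapping, sc, ctx)
  g <- materialize(g, sc)
  eg <- build_entity_graph(g, sc)
  base <- ctx$base
  sim <- tibble::tibble(
    from = mint_uri("compound", 44143441L, base),
    to = c(mint_uri("compound", 44143442L, base),
           mint_uri("compound", 44143438L, base),
           mint_uri("compound", 44143439L, base)),
    score = c(0.95, 0.92, 0.90)
  )
  eg <- add_similarity_edges(eg, sim, threshold = 0.85)
  list(graph = g, entity_graph = eg,
       query_compound = mint_uri("compound", 44143441L, base),
       target = mint_uri("protein", "KCNH2", base))
}
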