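# Independent oracles used across the suite. These deliberately re-derive
# expectations by brute force, along code paths disjoint from the package
# implementation they check.

# Naive fixpoint reasoner: apply every rule to every triple with plain
# loops until nothing changes. Returns the closed (s, p, o, is_literal) set.
naive_closure <- function(triples, schema) {
  curi <- function(x) scbgraph:::class_uri(schema, x)
  ns <- schema$namespaces
  # direct superclass map
  cl <- schema$classes
  parent_of <- stats::setNames(
    ifelse(is.na(cl$parent), NA_character_, vapply(
      ifelse(is.na(cl$parent), cl$name, cl$parent), curi, "")), curi(cl$name))
  pr <- schema$properties
  puri <- scbgraph:::expand_curie(pr$name, ns)
  inv <- stats::setNames(
    ifelse(is.na(pr$inverse), NA_character_,
           scbgraph:::expand_curie(ifelse(is.na(pr$inverse), pr$name,
                                          pr$inverse), ns)), puri)
  trans <- puri[pr$transitive]
  dom <- stats::setNames(ifelse(is.na(pr$domain), NA_character_, vapply(
    ifelse(is.na(pr$domain), "Interaction", pr$domain), curi, "")), puri)
  rng <- stats::setNames(ifelse(is.na(pr$range) | pr$kind != "object",
                                NA_character_, vapply(
    ifelse(is.na(pr$range) | pr$kind != "object", "Interaction", pr$range),
    curi, "")), puri)
  rdf_type <- scbgraph:::RDF_TYPE

  tt <- unique(triples[, c("subject", "predicate", "object", "is_literal")])
  repeat {
    new <- tt[0, ]
    for (k in seq_len(nrow(tt))) {
      s <- tt$subject[[k]]; p <- tt$predicate[[k]]; o <- tt$object[[k]]
      lit <- tt$is_literal[[k]]
      if (lit) next
      if (p == rdf_type && o %in% names(parent_of) &&
          !is.na(parent_of[[o]])) {
        new <- rbind(new, data.frame(subject = s, predicate = rdf_type,
                                     object = parent_of[[o]],
                                     is_literal = FALSE))
      }
      if (p %in% names(inv) && !is.na(inv[[p]])) {
        new <- rbind(new, data.frame(subject = o, predicate = inv[[p]],
                                     object = s, is_literal = FALSE))
      }
      if (p %in% trans) {
        nxt <- tt[tt$predicate == p & tt$subject == o & !tt$is_literal, ]
        if (nrow(nxt) > 0) {
          keep <- nxt$object != s
          if (any(keep)) {
            new <- rbind(new, data.frame(subject = s, predicate = p,
                                         object = nxt$object[keep],
                                         is_literal = FALSE))
          }
        }
      }
      if (p %in% names(dom) && !is.na(dom[[p]])) {
        new <- rbind(new, data.frame(subject = s, predicate = rdf_type,
                                     object = dom[[p]], is_literal = FALSE))
      }
      if (p %in% names(rng) && !is.na(rng[[p]])) {
        new <- rbind(new, data.frame(subject = o, predicate = rdf_type,
                                     object = rng[[p]], is_literal = FALSE))
      }
    }
    before <- nrow(tt)
    tt <- unique(rbind(tt, new))
    if (nrow(tt) == before) break
  }
  tt
}

triple_key <- function(tt) {
  sort(paste(tt$subject, tt$predicate, tt$object, tt$is_literal, sep = "\r"))
}

# Random instance graph over the schema vocabulary, for reasoning tests.
random_instance_graph <- function(schema, n_nodes = 30, seed = 1) {
  withr::with_seed(seed, {
    base <- scb_base_uri()
    curi <- function(x) scbgraph:::class_uri(schema, x)
    classes <- sample(schema$classes$name, n_nodes, replace = TRUE)
    nodes <- paste0(base, "inst", seq_len(n_nodes))
    tt <- scbgraph:::triple_rows(nodes, scbgraph:::RDF_TYPE,
                                 vapply(classes, curi, ""))
    props <- c("ro:has_participant", "ro:participates_in", "c2b2r:subDiseaseOf",
               "bp:evidence", "c2b2r:hasOutcome")
    n_edges <- n_nodes * 2
    e_from <- sample(nodes, n_edges, replace = TRUE)
    e_to <- sample(nodes, n_edges, replace = TRUE)
    e_p <- scbgraph:::expand_curie(
      sample(props, n_edges, replace = TRUE), schema$namespaces)
    keep <- e_from != e_to
    tt <- dplyr::bind_rows(
      tt, scbgraph:::triple_rows(e_from[keep], e_p[keep], e_to[keep]))
    semantic_graph(tt, schema$namespaces)
  })
}

# Exhaustive path oracle: enumerate node sequences with igraph over the
# simplified graph, then expand every parallel-edge label combination.
path_oracle <- function(g, a, b, max_len) {
  ed <- g$edges
  ig <- igraph::graph_from_data_frame(
    unique(ed[, c("from", "to")]), directed = FALSE,
    vertices = g$nodes$uri)
  ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE)
  ps <- igraph::all_simple_paths(ig, from = a, to = b, cutoff = max_len)
  out <- list()
  for (p in ps) {
    nodes <- names(p)
    label_opts <- lapply(seq_len(length(nodes) - 1L), function(i) {
      x <- nodes[[i]]; y <- nodes[[i + 1L]]
      sort(unique(ed$label[(ed$from == x & ed$to == y) |
                             (ed$from == y & ed$to == x)]))
    })
    combos <- expand.grid(label_opts, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      out[[length(out) + 1L]] <- list(nodes = nodes,
                                      labels = unlist(combos[r, ],
                                                      use.names = FALSE))
    }
  }
  out
}

path_key <- function(nodes, labels) {
  paste(paste(nodes, collapse = ">"), paste(labels, collapse = ">"), sep = "|")
}

# Random undirected labeled multigraph as an entity_graph.
random_entity_graph <- function(n_nodes = 30, n_edges = 45, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("urn:n%02d", seq_len(n_nodes))
    e1 <- sample(nodes, n_edges, replace = TRUE)
    e2 <- sample(nodes, n_edges, replace = TRUE)
    keep <- e1 != e2
    edges <- tibble::tibble(
      from = pmin(e1[keep], e2[keep]),
      to = pmax(e1[keep], e2[keep]),
      label = sample(c("binding", "similar_to", "shares_go_term"),
                     sum(keep), replace = TRUE),
      score = NA_real_
    ) |> dplyr::distinct()
    structure(list(
      nodes = tibble::tibble(uri = nodes, class = "x", label = NA_character_),
      edges = edges), class = "entity_graph")
  })
}

# Tiny ranking scenario: explicit drug-disease and drug-target tables with
# the expected ranking recomputed by dplyr counting.
random_ranking_fixture <- function(seed = 1, n_drugs = 8, n_targets = 6) {
  withr::with_seed(seed, {
    drugs <- tibble::tibble(
      dbid = sprintf("DB%03d", seq_len(n_drugs)),
      generic_name = sprintf("rdrug-%03d", seq_len(n_drugs)),
      cid = NA_integer_
    )
    targets <- sprintf("TG%03d_HUMAN", seq_len(n_targets))
    prot <- tibble::tibble(entry = targets,
                           protein_name = targets,
                           go_terms = "GO:0000001")
    linked <- sample(drugs$dbid, max(2, round(n_drugs * 0.6)))
    sider <- tibble::tibble(dbid = linked, disease_term = "heart disease")
    n_act <- n_drugs * 3
    acts <- tibble::tibble(
      dbid = sample(drugs$dbid, n_act, replace = TRUE),
      swissprot = sample(targets, n_act, replace = TRUE),
      action = "binder"
    ) |> dplyr::distinct()
    expected <- acts |>
      dplyr::filter(.data$dbid %in% linked) |>
      dplyr::distinct(.data$dbid, .data$swissprot) |>
      dplyr::count(.data$swissprot, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$swissprot)
    list(drugs = drugs, proteins = prot, sider = sider, actions = acts,
         expected = expected)
  })
}

rank_fixture_graph <- function(rf, schema) {
  mp <- default_mapping(include_ctd = FALSE)
  mp$sources <- mp$sources[c("uniprot", "drugbank_drugs", "drugbank_actions",
                             "sider")]
  mp$sources$drugbank_drugs$columns$cid <- NULL
  ctx <- resolution_context(do_terms = scbgraph:::fixed_disease_tree())
  materialize(annotate(
    list(uniprot = rf$proteins, drugbank_drugs = rf$drugs,
         drugbank_actions = rf$actions, sider = rf$sider),
    mp, schema, ctx), schema)
}

# Shared medium fixture: built once per test run, reused by several files.
shared_fixture_env <- new.env(parent = emptyenv())
get_shared_fixture <- function() {
  if (is.null(shared_fixture_env$fx)) {
    fx <- generate_fixtures(fixture_config(
      seed = 20260901L, n_compounds = 60L, n_drugs = 15L, n_proteins = 20L,
      n_interactions = 80L, n_side_effects = 25L))
    sc <- build_schema()
    ctx <- resolution_context(fx$lookup, fx$do_terms)
    g <- annotate(fx$sources, fx$mapping, sc, ctx)
    shared_fixture_env$fx <- fx
    shared_fixture_env$schema <- sc
    shared_fixture_env$graph <- g
    shared_fixture_env$materialized <- materialize(g, sc)
  }
  list(fx = shared_fixture_env$fx, schema = shared_fixture_env$schema,
       graph = shared_fixture_env$graph,
       materialized = shared_fixture_env$materialized)
}

# Parse a document with Python rdflib (the independent standards-conformant
# parser) and return its triple count, or NA if python is unusable.
rdflib_triple_count <- function(text, fmt) {
  tf <- tempfile(fileext = if (fmt == "turtle") ".ttl" else ".rdf")
  writeLines(text, tf, useBytes = TRUE)
  script <- sprintf(
    "import rdflib; g = rdflib.Graph(); g.parse('%s', format='%s'); print(len(g))",
    tf, if (fmt == "turtle") "turtle" else "xml")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return(NA_integer_)
  as.integer(utils::tail(out, 1))
}
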