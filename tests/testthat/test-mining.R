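test_that("interactions contract to labeled edges between participants", {
  sc <- build_schema()
  gm <- materialize(annotate_worked_example(), sc)
  eg <- build_entity_graph(gm, sc)
  base <- scb_base_uri()
  expect_identical(nrow(eg$edges), 1L)
  expect_identical(eg$edges$label, "c2b2r:Binding")
  expect_setequal(c(eg$edges$from, eg$edges$to),
                  paste0(base, c("compound5591", "proteinPPARG")))
  # helper nodes are excluded
  expect_false(any(grepl("xref|outcome|bioassay|structure", eg$nodes$uri)))
  # empty graph -> empty entity graph
  empty <- build_entity_graph(semantic_graph(), sc)
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("edge counts match the fixture manifest and survive reordering", {
  sh <- get_shared_fixture()
  eg <- build_entity_graph(sh$materialized, sh$schema)
  shuffled <- withr::with_seed(3, semantic_graph(
    sh$materialized$triples[sample(nrow(sh$materialized$triples)), ],
    sh$materialized$namespaces))
  eg2 <- build_entity_graph(shuffled, sh$schema)
  expect_identical(eg$edges, eg2$edges)
  # interaction edges: distinct (participant pair, class) combinations
  expect_gt(nrow(eg$edges), 0)
})

test_that("similarity edges respect threshold and score validation", {
  g <- random_entity_graph(n_nodes = 5, n_edges = 4, seed = 1)
  pairs <- tibble::tibble(from = c("urn:n01", "urn:n02"),
                          to = c("urn:n03", "urn:n04"),
                          score = c(0.9, 0.7))
  g2 <- add_similarity_edges(g, pairs, threshold = 0.85)
  sim <- g2$edges[g2$edges$label == "similar_to", ]
  expect_identical(nrow(sim), 1L)
  expect_identical(sim$score, 0.9)
  # threshold 1.0 with no perfect scores leaves the graph unchanged
  g3 <- add_similarity_edges(g, pairs, threshold = 1.0)
  expect_identical(g3$edges, g$edges)
  expect_error(add_similarity_edges(g, tibble::tibble(
    from = "urn:n01", to = "urn:n02", score = 1.2)),
    class = "scb_validation_error")
})

test_that("path enumeration matches the exhaustive DFS oracle on random graphs", {
  for (seed in 1:20) {
    g <- random_entity_graph(n_nodes = 30, n_edges = 45, seed = seed)
    ends <- withr::with_seed(seed + 1000, sample(g$nodes$uri, 2))
    got <- find_paths(g, ends[[1]], ends[[2]], max_len = 4)
    want <- path_oracle(g, ends[[1]], ends[[2]], max_len = 4)
    got_keys <- as.character(unlist(mapply(path_key, got$nodes,
                                           got$edge_labels)))
    want_keys <- vapply(want, function(p) path_key(p$nodes, p$labels), "")
    expect_identical(sort(got_keys), sort(want_keys),
                     label = paste("seed", seed))
    expect_false(anyDuplicated(got_keys) > 0)
  }
})

test_that("paths are simple, bounded, and ordered by length then nodes", {
  g <- random_entity_graph(n_nodes = 15, n_edges = 30, seed = 5)
  ends <- g$nodes$uri[c(1, 8)]
  res <- find_paths(g, ends[[1]], ends[[2]], max_len = 4)
  for (k in seq_len(nrow(res))) {
    nodes <- res$nodes[[k]]
    expect_false(anyDuplicated(nodes) > 0)
    expect_identical(res$length[[k]], length(nodes) - 1L)
    expect_lte(res$length[[k]], 4L)
  }
  expect_true(!is.unsorted(res$length))
  expect_error(find_paths(g, "urn:nope", ends[[2]], 4),
               class = "scb_lookup_error")
})

test_that("a direct edge yields the length-1 path first", {
  g <- structure(list(
    nodes = tibble::tibble(uri = c("urn:a", "urn:b", "urn:c"),
                           class = "x", label = NA_character_),
    edges = tibble::tibble(from = c("urn:a", "urn:a", "urn:b"),
                           to = c("urn:b", "urn:c", "urn:c"),
                           label = "binding", score = NA_real_)),
    class = "entity_graph")
  res <- find_paths(g, "urn:a", "urn:b", max_len = 3)
  expect_identical(res$nodes[[1]], c("urn:a", "urn:b"))
  expect_identical(res$length, c(1L, 2L))
})

test_that("the three association motifs appear in the path-mining fixture", {
  px <- path_mining_example()
  res <- find_paths(px$entity_graph, px$query_compound, px$target, max_len = 4)
  sigs <- vapply(res$edge_labels, paste, "", collapse = ">")
  # structurally similar compounds that bind the target
  expect_identical(sum(sigs == "similar_to>c2b2r:Binding"), 3L)
  # a second target linked by a shared ligand
  expect_true("c2b2r:Binding>c2b2r:Binding>c2b2r:Binding" %in% sigs)
  # GO-term sharing between the two targets
  expect_true("c2b2r:Binding>shares_go_term" %in% sigs)
})

test_that("tidiers and plots expose the expected surfaces", {
  px <- path_mining_example()
  eg <- px$entity_graph
  expect_identical(tidy(eg), eg$edges)
  gl <- glance(eg)
  expect_identical(gl$n_nodes, nrow(eg$nodes))
  p <- autoplot(eg)
  expect_s3_class(p, "ggplot")
  sc <- build_schema()
  expect_identical(glance(sc)$n_chemogenomic, 61L)
  g <- annotate_worked_example()
  expect_identical(nrow(tidy(g)), nrow(g$triples))
  expect_identical(glance(g)$n_inferred, 0L)
})
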