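test_that("catalog term sizes respect the requested range and forced sizes", {
  spec <- synthetic_spec(n_genes = 100, n_terms = 5,
                         term_size_range = c(10, 10), n_classes = 2,
                         class_sizes = c(5, 5), drivers_per_class = 1,
                         seed = 3)
  cat5 <- build_annotation_catalog(spec)
  expect_length(cat5$terms, 5)
  expect_true(all(lengths(cat5$terms) == 10))
  expect_true(all(vapply(cat5$terms,
                         function(g) !anyDuplicated(g) &&
                           all(g %in% cat5$universe), logical(1))))

  spec2 <- synthetic_spec(n_genes = 2000, n_terms = 150,
                          term_size_range = c(10, 200), seed = 1)
  cat150 <- build_annotation_catalog(spec2)
  sizes <- lengths(cat150$terms)
  expect_true(all(sizes >= 10 & sizes <= 200))
  expect_length(sizes, 150)
})

test_that("generator is fully deterministic under the spec seed", {
  spec <- small_spec()
  c1 <- build_annotation_catalog(spec)
  c2 <- build_annotation_catalog(spec)
  expect_identical(c1, c2)
  expect_identical(simulate_cohort(spec, c1), simulate_cohort(spec, c1))
  g1 <- build_interaction_graph(spec, c1)
  g2 <- build_interaction_graph(spec, c1)
  expect_identical(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_genes = 5, term_size_range = c(2, 10)),
               class = "tumorsig_invalid_spec")
  expect_error(synthetic_spec(n_terms = 2, drivers_per_class = 3),
               class = "tumorsig_invalid_spec")
  expect_error(synthetic_spec(class_sizes = c(1, 5), n_classes = 2),
               class = "tumorsig_invalid_spec")
  expect_error(synthetic_spec(signal_fraction = 1.2),
               class = "tumorsig_invalid_spec")
})

test_that("cohorts hit the requested class sizes, including an
           11-type imbalanced layout", {
  sizes <- c(100, 513, 499, 276, 306, 473, 201, 230, 177, 456, 247)
  spec <- synthetic_spec(n_genes = 500, n_terms = 30,
                         term_size_range = c(5, 50), n_classes = 11,
                         class_sizes = sizes, drivers_per_class = 1,
                         burden_mean = 10, seed = 5)
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  expect_equal(nrow(cohort$profiles), 3478)
  expect_equal(as.integer(table(factor(cohort$profiles$class_label,
                                       cohort$classes))), sizes)
  expect_false(anyDuplicated(cohort$profiles$sample_id) > 0)
  expect_named(cohort$truth, cohort$classes)
  expect_true(all(unlist(cohort$profiles$genes) %in% cohort$universe))
})

test_that("signal_fraction = 1 with one driver term confines mutations to it", {
  spec <- synthetic_spec(n_genes = 200, n_terms = 8,
                         term_size_range = c(20, 40), n_classes = 2,
                         class_sizes = c(10, 10), drivers_per_class = 1,
                         signal_fraction = 1, seed = 11)
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  for (k in cohort$classes) {
    driver_genes <- unlist(catalog$terms[cohort$truth[[k]]])
    rows <- cohort$profiles[cohort$profiles$class_label == k, ]
    expect_true(all(unlist(rows$genes) %in% driver_genes))
  }
})

test_that("signal_fraction = 0 gives uniform gene draws", {
  spec <- synthetic_spec(n_genes = 100, n_terms = 5,
                         term_size_range = c(10, 20), n_classes = 2,
                         class_sizes = c(600, 600), drivers_per_class = 1,
                         signal_fraction = 0, burden_mean = 90,
                         burden_dispersion = 50, seed = 13)
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  pooled <- table(factor(unlist(cohort$profiles$genes),
                         levels = cohort$universe))
  # dedup within samples thins high-burden draws slightly but symmetrically;
  # pooled gene usage should not reject uniformity
  gof <- suppressWarnings(stats::chisq.test(as.numeric(pooled)))
  expect_gt(gof$p.value, 0.01)
})

test_that("driver enrichment exceeds the null expectation at
           signal_fraction 0.5", {
  spec <- synthetic_spec(n_genes = 1000, n_terms = 40,
                         term_size_range = c(20, 80), n_classes = 3,
                         class_sizes = c(60, 60, 60), drivers_per_class = 2,
                         signal_fraction = 0.5, seed = 17)
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  for (k in cohort$classes) {
    union_k <- unique(unlist(catalog$terms[cohort$truth[[k]]]))
    p0 <- length(union_k) / length(cohort$universe)
    genes <- unlist(cohort$profiles$genes[cohort$profiles$class_label == k])
    bt <- stats::binom.test(sum(genes %in% union_k), length(genes), p = p0,
                            alternative = "greater")
    expect_lt(bt$p.value, 0.01)
  }
})

test_that("interaction graph honors forced edge probabilities and weights", {
  # single 4-gene term, within prob 1, background 0 -> exactly that 4-clique
  spec <- synthetic_spec(n_genes = 20, n_terms = 1,
                         term_size_range = c(4, 4), n_classes = 2,
                         class_sizes = c(5, 5), drivers_per_class = 1,
                         edge_prob_within_term = 1,
                         edge_prob_background = 0, seed = 19)
  catalog <- build_annotation_catalog(spec)
  g <- build_interaction_graph(spec, catalog)
  expect_equal(igraph::ecount(g), 6)
  expect_setequal(names(which(igraph::degree(g) > 0)), catalog$terms[[1]])
  expect_true(all(igraph::degree(g)[catalog$terms[[1]]] == 3))

  w <- small_world()
  weights <- igraph::E(w$graph)$weight
  expect_true(all(weights > 0.15 & weights <= 0.999))

  # within-term connectivity dominates background
  deg <- igraph::degree(w$graph)
  in_term <- names(deg) %in% unique(unlist(w$catalog$terms))
  expect_gt(mean(deg[in_term]), mean(deg[!in_term]))
})

test_that("cohort/catalog/graph/feature round-trips preserve content", {
  w <- small_world()
  td <- withr::local_tempdir()
  f_cohort <- file.path(td, "cohort.tsv")
  write_cohort(w$cohort, f_cohort)
  back <- read_cohort(f_cohort, universe = w$cohort$universe)
  expect_identical(back$profiles$sample_id, w$cohort$profiles$sample_id)
  expect_identical(back$profiles$class_label, w$cohort$profiles$class_label)
  expect_identical(lapply(back$profiles$genes, sort),
                   lapply(w$cohort$profiles$genes, sort))

  f_gmt <- file.path(td, "catalog.gmt")
  write_gmt(w$catalog, f_gmt)
  cat_back <- read_gmt(f_gmt, universe = w$catalog$universe)
  expect_identical(cat_back$terms, w$catalog$terms)
  expect_identical(cat_back$namespace, w$catalog$namespace)

  f_edges <- file.path(td, "edges.tsv")
  write_edges(w$graph, f_edges)
  g_back <- read_edges(f_edges)
  expect_equal(igraph::ecount(g_back), igraph::ecount(w$graph))

  f_feat <- file.path(td, "features.tsv")
  write_features(w$enr, f_feat)
  feat_back <- read_features(f_feat)
  expect_equal(as.data.frame(feat_back), as.data.frame(w$enr),
               tolerance = 1e-12)
  expect_identical(feature_types(feat_back), feature_types(w$enr))
})
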