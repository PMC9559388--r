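test_that("log-space tail matches exact enumeration on hand-checked cases", {
  expect_identical(log10_hypergeom_tail(20, 5, 4, 0), 0)
  # C(3,3)C(7,0)/C(10,3) = 1/120
  expect_equal(log10_hypergeom_tail(10, 3, 3, 3), log10(1 / 120),
               tolerance = 1e-12)
  # (C(5,2)C(15,2) + C(5,3)C(15,1) + C(5,4)C(15,0)) / C(20,4) = 1205/4845
  expect_equal(log10_hypergeom_tail(20, 5, 4, 2), log10(1205 / 4845),
               tolerance = 1e-12)
})

test_that("tail evaluation stays finite far beyond double underflow", {
  lg <- log10_hypergeom_tail(20000, 200, 200, 200)
  expect_true(is.finite(lg))
  expect_lt(lg, -300)  # p far below 1e-300: plain summation would underflow
})

test_that("domain violations name the offending argument", {
  expect_error(log10_hypergeom_tail(10, 11, 3, 1),
               class = "tumorsig_domain_error")
  expect_error(log10_hypergeom_tail(10, 3, 11, 1),
               class = "tumorsig_domain_error")
  expect_error(log10_hypergeom_tail(10, 3, 3, 4),
               class = "tumorsig_domain_error")
  expect_error(log10_hypergeom_tail(10, 3, 3, -1), regexp = "`m`")
})

test_that("scores are nonnegative, capped, and nondecreasing in the overlap", {
  for (m in 0:8) {
    if (m > 0) {
      expect_gte(-log10_hypergeom_tail(50, 10, 8, m),
                 -log10_hypergeom_tail(50, 10, 8, max(0, m - 1)))
    }
  }
  w <- small_world()
  vals <- as.matrix(w$enr[, feature_names(w$enr)])
  expect_true(all(vals >= 0))
  expect_true(all(vals <= 300))
})

test_that("enrichment_score handles edge cases per contract", {
  w <- small_world()
  term1 <- names(w$catalog$terms)[1]
  outside <- setdiff(w$catalog$universe, w$catalog$terms[[term1]])[1:5]
  expect_identical(enrichment_score(outside, term1, w$catalog), 0)
  expect_error(enrichment_score(outside, "nope", w$catalog),
               class = "tumorsig_lookup_error")
  expect_warning(
    s <- enrichment_score("not_a_gene", term1, w$catalog),
    regexp = "universe")
  expect_identical(s, 0)

  # a sample equal to a term's gene set beats any gene-disjoint sample
  exact <- enrichment_score(w$catalog$terms[[term1]], term1, w$catalog)
  expect_gt(exact, enrichment_score(outside, term1, w$catalog))

  # matches the hand-enumerated value through the catalog route
  mini <- tumorsig:::new_annotation_catalog(
    sprintf("g%02d", 1:20), list(tm = sprintf("g%02d", 1:5)))
  expect_equal(enrichment_score(c("g01", "g02", "g10", "g11"), "tm", mini),
               -log10(1205 / 4845), tolerance = 1e-12)
})

test_that("cohort encoding has catalog column order and no cross-sample
           state", {
  w <- small_world()
  expect_identical(feature_names(w$enr), names(w$catalog$terms))
  expect_identical(w$enr$sample_id, w$cohort$profiles$sample_id)
  expect_true(all(feature_types(w$enr) == "enrichment"))

  # permuting the cohort permutes rows identically
  perm <- rev(seq_len(nrow(w$cohort$profiles)))
  shuffled <- tumorsig:::new_cohort(w$cohort$profiles[perm, ],
                                    w$cohort$universe, w$cohort$classes,
                                    w$cohort$truth)
  enr2 <- encode_enrichment(shuffled, w$catalog)
  expect_equal(as.data.frame(enr2), as.data.frame(w$enr[perm, ]),
               tolerance = 1e-12)

  # spot-check matrix entries against the scalar scorer
  for (i in c(1, 20, 75)) {
    for (tm in names(w$catalog$terms)[c(1, 10, 20)]) {
      expect_equal(w$enr[[tm]][i],
                   enrichment_score(w$cohort$profiles$genes[[i]], tm,
                                    w$catalog),
                   tolerance = 1e-12)
    }
  }
})

test_that("driver-term scores separate the owning class", {
  spec <- synthetic_spec(n_genes = 1000, n_terms = 40,
                         term_size_range = c(20, 80), n_classes = 4,
                         class_sizes = c(150, 150, 150, 150),
                         drivers_per_class = 2, signal_fraction = 0.6,
                         seed = 23)
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  enr <- encode_enrichment(cohort, catalog)
  y <- cohort$profiles$class_label
  hits <- 0; total <- 0
  for (k in cohort$classes) {
    for (tm in cohort$truth[[k]]) {
      total <- total + 1
      own <- mean(enr[[tm]][y == k])
      other <- mean(enr[[tm]][y != k])
      if (own > other) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
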