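test_that("corpus sentences carry exactly each sample's gene set", {
  w <- small_world()
  corpus <- build_corpus(w$cohort, seed = 2)
  expect_length(corpus, nrow(w$cohort$profiles))
  for (i in seq_along(corpus)) {
    expect_setequal(corpus[[i]], w$cohort$profiles$genes[[i]])
    expect_false(anyDuplicated(corpus[[i]]) > 0)
  }
  expect_identical(corpus, build_corpus(w$cohort, seed = 2))
  # a singleton gene set is a one-token sentence
  mini <- tumorsig:::new_cohort(
    tibble::tibble(sample_id = "s1", class_label = "a", genes = list("G1")),
    universe = "G1", classes = "a")
  expect_identical(build_corpus(mini, seed = 1), list("G1"))
})

test_that("min_count filters rare tokens; empty vocabulary errors", {
  corpus <- list(c("A", "B"), c("A", "B"), c("A", "C"))
  tab <- train_gene_embeddings(corpus, dim = 4, window = 2, epochs = 2,
                               min_count = 2, seed = 1)
  expect_setequal(rownames(tab$vectors), c("A", "B"))
  expect_error(train_gene_embeddings(corpus, dim = 4, min_count = 10),
               class = "tumorsig_config_error")
})

test_that("training is deterministic and separates co-occurring genes", {
  # planted structure: G1,G2 always together; G3 only ever alone
  corpus <- c(rep(list(c("G1", "G2")), 40), rep(list("G3"), 40),
              rep(list(c("G4", "G5", "G6")), 20))
  t1 <- train_gene_embeddings(corpus, dim = 16, window = 8, epochs = 30,
                              seed = 9)
  t2 <- train_gene_embeddings(corpus, dim = 16, window = 8, epochs = 30,
                              seed = 9)
  expect_identical(t1$vectors, t2$vectors)

  seps <- vapply(1:5, function(s) {
    tt <- train_gene_embeddings(corpus, dim = 16, window = 8, epochs = 30,
                                seed = s)
    embedding_cosine(tt, "G1", "G2") > embedding_cosine(tt, "G1", "G3")
  }, logical(1))
  expect_gte(sum(seps), 4)
})

test_that("sample aggregation is the exact mean of member vectors", {
  w <- small_world()
  corpus <- build_corpus(w$cohort, seed = 1)
  tab <- train_gene_embeddings(corpus, dim = 8, epochs = 3, seed = 1)
  txt <- embed_samples_text(w$cohort, tab)
  expect_identical(dim(txt), c(nrow(w$cohort$profiles), 9L))
  expect_true(all(feature_types(txt) == "text"))
  expect_false(anyNA(txt))

  M <- as.matrix(txt[, feature_names(txt)])
  for (i in c(1, 10, 40)) {
    g <- intersect(w$cohort$profiles$genes[[i]], rownames(tab$vectors))
    expect_equal(unname(M[i, ]),
                 unname(colMeans(tab$vectors[g, , drop = FALSE])),
                 tolerance = 1e-9)
    # envelope: each coordinate within member min/max
    env_lo <- apply(tab$vectors[g, , drop = FALSE], 2, min)
    env_hi <- apply(tab$vectors[g, , drop = FALSE], 2, max)
    expect_true(all(M[i, ] >= env_lo - 1e-12 & M[i, ] <= env_hi + 1e-12))
  }

  # single- and two-gene samples: exact vector and midpoint
  g1 <- rownames(tab$vectors)[1]; g2 <- rownames(tab$vectors)[2]
  mini <- tumorsig:::new_cohort(
    tibble::tibble(sample_id = c("s1", "s2"), class_label = c("a", "a"),
                   genes = list(g1, c(g1, g2))),
    universe = w$cohort$universe, classes = "a")
  res <- embed_samples_text(mini, tab)
  Mm <- as.matrix(res[, feature_names(res)])
  expect_equal(unname(Mm[1, ]), unname(tab$vectors[g1, ]), tolerance = 1e-9)
  expect_equal(unname(Mm[2, ]),
               unname((tab$vectors[g1, ] + tab$vectors[g2, ]) / 2),
               tolerance = 1e-9)

  # permutation invariance in the gene order
  mini2 <- tumorsig:::new_cohort(
    tibble::tibble(sample_id = c("s1"), class_label = "a",
                   genes = list(c(g2, g1))),
    universe = w$cohort$universe, classes = "a")
  res2 <- embed_samples_text(mini2, tab)
  expect_equal(unname(as.matrix(res2[, feature_names(res2)])[1, ]),
               unname(Mm[2, ]), tolerance = 1e-12)
})

test_that("samples with no embedded genes get zero rows with a warning", {
  tab <- train_gene_embeddings(list(c("A", "B"), c("A", "B")), dim = 4,
                               epochs = 2, seed = 1)
  mini <- tumorsig:::new_cohort(
    tibble::tibble(sample_id = "s1", class_label = "a", genes = list("ZZZ")),
    universe = c("A", "B", "ZZZ"), classes = "a")
  expect_warning(res <- embed_samples_text(mini, tab), regexp = "zero")
  expect_true(all(as.matrix(res[, feature_names(res)]) == 0))
})

test_that("embedding tables round-trip through TSV", {
  tab <- train_gene_embeddings(list(c("A", "B", "C"), c("A", "C")),
                               dim = 6, epochs = 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(tab, f)
  back <- read_embeddings(f)
  expect_equal(unname(back$vectors[rownames(tab$vectors), ]),
               unname(tab$vectors), tolerance = 1e-6)
})
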