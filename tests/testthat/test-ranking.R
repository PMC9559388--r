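test_that("lasso ranks a class indicator first and zeros last", {
  set.seed(11)
  n <- 300
  y <- rep(c("a", "b", "c"), each = n / 3)
  X <- cbind(sig = as.numeric(y == "a") + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 10), n,
                    dimnames = list(NULL, paste0("noise", 1:10))),
             flat = rep(2, n))
  rl <- rank_lasso(X, y, seed = 1)
  expect_identical(rl$feature[1], "sig")
  expect_setequal(rl$feature, colnames(X))
  expect_true(all(diff(rl$score) <= 1e-12))
  # constant feature scores 0 and sits after every nonzero-score feature
  expect_identical(rl$score[rl$feature == "flat"], 0)
  expect_error(rank_lasso(cbind(X[, 1:2], bad = c(Inf, rep(1, n - 1))), y),
               regexp = "finite")
})

test_that("mRMR greedy equals the brute-force oracle", {
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 150
    d <- 12
    y <- factor(rep_len(c("a", "b", "c"), n))
    X <- matrix(rnorm(n * d), n, dimnames = list(NULL, paste0("f", 1:d)))
    X[, 1] <- X[, 1] + 2 * as.integer(y)
    X[, 2] <- X[, 2] + as.integer(y == "b")
    rl <- rank_mrmr(X, y)
    expect_identical(rl$feature, oracle_mrmr(X, y))
  }
})

test_that("mRMR never picks a duplicate of the first selection second", {
  set.seed(21)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  strong <- as.numeric(y == "a") + rnorm(n, sd = 0.05)
  weak <- as.numeric(y == "a") * 0.5 + rnorm(n, sd = 1)
  X <- cbind(strong = strong, clone = strong, weak = weak,
             indep = rnorm(n))
  rl <- rank_mrmr(X, y)
  expect_identical(rl$feature[1], "strong")
  expect_false(rl$feature[2] == "clone")
})

test_that("MCFS drops zero-RI features and ranks the informative one top", {
  d <- make_informative_design(n = 150, n_inf = 1, n_noise = 20, shift = 3,
                               seed = 31)
  tops <- vapply(1:5, function(s) {
    rl <- rank_mcfs(d$x, d$y, mcfs_params(c = 20, s = 50, m_proj = 5,
                                          seed = s))
    expect_true(all(rl$score > 0))
    expect_true(all(diff(rl$score) <= 1e-12))
    expect_setequal(c(rl$feature, ranking_meta(rl)$dropped), colnames(d$x))
    rl$feature[1] == "inf01"
  }, logical(1))
  expect_gte(sum(tops), 4)
})

test_that("MCFS is deterministic and a never-projected feature is absent", {
  d <- make_informative_design(n = 100, n_inf = 2, n_noise = 6, seed = 41)
  p <- mcfs_params(c = 3, s = 4, m_proj = 2, seed = 5)
  r1 <- rank_mcfs(d$x, d$y, p)
  r2 <- rank_mcfs(d$x, d$y, p)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # with 3*4=12 projections of 2 of 8 features, absences are expected;
  # anything dropped must have appeared in no split
  expect_setequal(c(r1$feature, ranking_meta(r1)$dropped), colnames(d$x))
  expect_error(rank_mcfs(d$x, d$y, mcfs_params(m_proj = 100)),
               regexp = "m_proj")
})

test_that("GBDT split counts are conserved and unused features score 0", {
  d <- make_informative_design(n = 200, n_inf = 2, n_noise = 10, shift = 3,
                               seed = 51)
  X <- cbind(d$x, flat = rep(0, 200))
  rl <- rank_gbdt(X, d$y, n_trees = 30, seed = 1)
  expect_setequal(rl$feature, colnames(X))
  expect_true(all(diff(rl$score) <= 1e-12))
  expect_identical(rl$score[rl$feature == "flat"], 0)
  # conservation: scores sum to the ensemble's total split count
  bst_total <- sum(rl$score)
  expect_gt(bst_total, 0)
  expect_true("inf01" %in% rl$feature[1:4])
  r2 <- rank_gbdt(X, d$y, n_trees = 30, seed = 1)
  expect_identical(as.data.frame(rl), as.data.frame(r2))
})

test_that("the four rankers give valid, non-identical lists on one cohort", {
  w <- small_world()
  y <- w$y
  kept <- feature_names(w$enr)
  rks <- rank_all(w$enr, y, seed = 1,
                  mcfs = mcfs_params(c = 5, s = 20, m_proj = 4, seed = 1))
  expect_named(rks, c("lasso", "mrmr", "mcfs", "gbdt"))
  for (m in names(rks)) {
    expect_true(all(rks[[m]]$feature %in% kept))
    expect_false(anyDuplicated(rks[[m]]$feature) > 0)
  }
  # methods complement each other: no two orderings coincide
  ords <- lapply(rks, function(r) r$feature)
  pairs <- utils::combn(names(ords), 2)
  same <- apply(pairs, 2, function(p) identical(ords[[p[1]]], ords[[p[2]]]))
  expect_false(any(same))
})
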