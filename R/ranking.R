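#' Ranked feature lists
#'
#' All four rankers return a `ranked_list`: a tibble with columns `rank`,
#' `feature`, `score`, plus attributes `method` (one of `"lasso"`, `"mrmr"`,
#' `"mcfs"`, `"gbdt"`) and `meta` (parameters, seed, and any features
#' dropped for zero importance).
#'
#' @name ranked_list
NULL

new_ranked_list <- function(features, scores, method, meta = list()) {
  stopifnot(!anyDuplicated(features), length(features) == length(scores))
  structure(tibble(rank = seq_along(features), feature = features,
                   score = as.numeric(scores)),
            method = method, meta = meta,
            class = c("ranked_list", class(tibble())))
}

#' @rdname ranked_list
#' @param x A `ranked_list`.
#' @export
ranking_method <- function(x) attr(x, "method")

#' @rdname ranked_list
#' @export
ranking_meta <- function(x) attr(x, "meta")

# descending stable order: ties and exact zeros keep input order
rank_desc_stable <- function(features, scores) {
  o <- order(-scores, seq_along(scores))
  list(features = features[o], scores = scores[o])
}

# standardize columns, zero-variance columns become all-zero
standardize_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  scale(X, center = mu, scale = sdv)
}

#' Rank features by one-vs-rest L1-penalized regression
#'
#' Features are standardized internally; for each class an L1-penalized
#' linear regression is fit against the 0/1 class indicator (lambda by
#' seeded 5-fold cross-validation), and a feature's score is its maximum
#' absolute coefficient across classes. Exact-zero scores keep input order
#' at the tail.
#'
#' @param x A `feature_tbl` or numeric matrix.
#' @param y Class labels.
#' @param seed Integer seed (cross-validation folds).
#' @param nfolds Folds for the internal lambda selection.
#' @return A `ranked_list` with `method = "lasso"`.
#' @export
rank_lasso <- function(x, y, seed = 1L, nfolds = 5) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  if (!all(is.finite(X))) abort("Non-finite feature values.")
  y <- factor(y)
  Xs <- standardize_cols(X)
  feats <- colnames(X)
  score <- setNames(rep(0, ncol(X)), feats)
  foldid <- with_seed(derive_seed(seed, 81L),
                      sample(rep_len(seq_len(nfolds), nrow(X))))
  for (cl in levels(y)) {
    ind <- as.numeric(y == cl)
    cv <- glmnet::cv.glmnet(Xs, ind, family = "gaussian", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    b <- abs(as.numeric(coef(cv, s = "lambda.min"))[-1])
    score <- pmax(score, b)
  }
  r <- rank_desc_stable(feats, unname(score))
  new_ranked_list(r$features, r$scores, "lasso",
                  meta = list(seed = seed, nfolds = nfolds))
}

# 3-state discretization at mean +/- one standard deviation
discretize3 <- function(v) {
  mu <- mean(v); s <- sd(v)
  1L + (v > mu - s) + (v > mu + s)
}

mi_pair <- function(a, ka, b, kb) {
  n <- length(a)
  jt <- tabulate(a + ka * (b - 1L), ka * kb)
  p <- jt / n
  pa <- tabulate(a, ka) / n
  pb <- tabulate(b, kb) / n
  pe <- as.vector(outer(pa, pb))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pe[nz]))
}

#' Rank features by minimum-redundancy-maximum-relevance
#'
#' Greedy mRMR in the difference (MID) form on features discretized to three
#' states at mean +/- one standard deviation. The first pick maximizes mutual
#' information with the labels; each later pick maximizes
#' `I(f; y) - mean over selected s of I(f; s)`. Scores record the greedy
#' criterion at selection time. Ties break by input order.
#'
#' @param x A `feature_tbl` or numeric matrix.
#' @param y Class labels.
#' @param n_select How many features to rank (default: all).
#' @return A `ranked_list` with `method = "mrmr"`.
#' @export
rank_mrmr <- function(x, y, n_select = NULL) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  y <- factor(y)
  d <- ncol(X)
  if (is.null(n_select)) n_select <- d
  if (n_select <= 0) abort("`n_select` must be positive.")
  stopifnot(n_select <= d)
  D <- apply(X, 2, discretize3)
  yk <- as.integer(y)
  K <- nlevels(y)
  rel <- vapply(seq_len(d), function(j) mi_pair(D[, j], 3L, yk, K),
                numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- rep(0, d)
  remaining <- seq_len(d)
  for (step in seq_len(n_select)) {
    crit <- if (step == 1) rel[remaining] else {
      rel[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- remaining[which.max(crit)]  # which.max: first max = input order
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && step < n_select) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining,
               function(j) mi_pair(D[, j], 3L, D[, pick], 3L), numeric(1))
    }
  }
  new_ranked_list(colnames(X)[selected], scores, "mrmr",
                  meta = list(n_select = n_select))
}

#' Parameters for Monte Carlo feature selection
#'
#' @param c Number of dataset resamplings.
#' @param s Random feature projections (hence trees) per resampling.
#' @param m_proj Features per projection (default `ceiling(0.05 * d)` at fit
#'   time).
#' @param u,v Exponents on the tree's class-balanced test accuracy and on
#'   the node-size fraction.
#' @param train_fraction Stratified train share per resampling.
#' @param seed Integer seed.
#' @return An `mcfs_params` list.
#' @export
mcfs_params <- function(c = 20, s = 100, m_proj = NULL, u = 1, v = 1,
                        train_fraction = 0.66, seed = 1L) {
  stopifnot(c >= 1, s >= 1, u > 0, v > 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(c = as.integer(c), s = as.integer(s), m_proj = m_proj,
                 u = u, v = v, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "mcfs_params")
}

# entropy (bits) from class counts
entropy_counts <- function(cnt) {
  cnt <- cnt[cnt > 0]
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

# per-feature sum over internal nodes of IG * (n_node / n_root)^v
tree_ig_contrib <- function(fit, v) {
  fr <- fit$frame
  internal <- which(fr$var != "<leaf>")
  if (length(internal) == 0) return(numeric(0))
  nodes <- as.integer(rownames(fr))
  K <- (ncol(fr$yval2) - 2) / 2
  counts <- fr$yval2[, 1 + seq_len(K), drop = FALSE]
  n_root <- fr$n[1]
  contrib <- numeric(length(internal))
  for (i in seq_along(internal)) {
    r <- internal[i]
    left <- match(2L * nodes[r], nodes)
    right <- match(2L * nodes[r] + 1L, nodes)
    np <- fr$n[r]
    ig <- entropy_counts(counts[r, ]) -
      fr$n[left] / np * entropy_counts(counts[left, ]) -
      fr$n[right] / np * entropy_counts(counts[right, ])
    contrib[i] <- max(ig, 0) * (np / n_root)^v
  }
  tapply(contrib, fr$var[internal], sum)
}

#' Rank features by Monte Carlo feature selection
#'
#' Trains `c * s` decision trees, each on a random projection of `m_proj`
#' features over a stratified train split, and accumulates each feature's
#' relative importance: the tree's class-balanced test accuracy to the power
#' `u` times the sum over the tree's splits on that feature of information
#' gain weighted by `(node size / tree size)^v`. Features whose RI is
#' exactly 0 (never sampled or never used in a split) are dropped from the
#' list and recorded in `meta$dropped`.
#'
#' @param x A `feature_tbl` or numeric matrix.
#' @param y Class labels.
#' @param params An [mcfs_params()].
#' @return A `ranked_list` with `method = "mcfs"`.
#' @export
rank_mcfs <- function(x, y, params = mcfs_params()) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  y <- factor(y)
  d <- ncol(X)
  m_proj <- params$m_proj %||% ceiling(0.05 * d)
  if (m_proj > d) abort("`m_proj` exceeds the number of features.")
  feats <- colnames(X)
  ri <- setNames(rep(0, d), feats)
  ctrl <- rpart::rpart.control(minsplit = 5, cp = 0, xval = 0,
                               maxsurrogate = 0, maxcompete = 0)
  with_seed(derive_seed(params$seed, 91L), {
    for (ci in seq_len(params$c)) {
      tr <- unlist(lapply(split(seq_along(y), y), function(idx) {
        n_tr <- min(max(1L, round(params$train_fraction * length(idx))),
                    length(idx) - 1L)
        sample(idx, n_tr)
      }), use.names = FALSE)
      te <- setdiff(seq_along(y), tr)
      for (si in seq_len(params$s)) {
        pj <- sample(d, m_proj)
        df_tr <- as.data.frame(X[tr, pj, drop = FALSE])
        df_tr$.y <- y[tr]
        fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class",
                            control = ctrl)
        pred <- predict(fit, as.data.frame(X[te, pj, drop = FALSE]),
                        type = "class")
        rec <- vapply(levels(y)[table(y[te]) > 0], function(cl) {
          mean(pred[y[te] == cl] == cl)
        }, numeric(1))
        wacc <- mean(rec)
        contrib <- tree_ig_contrib(fit, params$v)
        if (length(contrib) > 0) {
          ri[names(contrib)] <- ri[names(contrib)] +
            wacc^params$u * as.numeric(contrib)
        }
      }
    }
  })
  keep <- ri > 0
  r <- rank_desc_stable(feats[keep], unname(ri[keep]))
  new_ranked_list(r$features, r$scores, "mcfs",
                  meta = c(unclass(params),
                           list(m_proj = m_proj, dropped = feats[!keep])))
}

#' Rank features by gradient-boosted tree split counts
#'
#' Trains a gradient-boosted decision-tree ensemble (histogram-based,
#' leaf-wise growth with 31 leaves, learning rate 0.1) on the multiclass
#' problem and scores every feature by the total number of splits that use
#' it across all trees. Unused features score 0 and keep input order at the
#' tail.
#'
#' @param x A `feature_tbl` or numeric matrix.
#' @param y Class labels.
#' @param n_trees Boosting rounds.
#' @param seed Integer seed.
#' @return A `ranked_list` with `method = "gbdt"`.
#' @export
rank_gbdt <- function(x, y, n_trees = 100, seed = 1L) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  y <- factor(y)
  stopifnot(n_trees >= 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(y),
                  eta = 0.1, grow_policy = "lossguide", max_leaves = 31,
                  max_depth = 0, tree_method = "hist", nthread = 1,
                  seed = derive_seed(seed, 97L)),
    data = dtrain, nrounds = n_trees, verbose = 0)
  tr <- xgboost::xgb.model.dt.tree(model = bst)
  used <- tr$Feature[tr$Feature != "Leaf"]
  cnt <- table(used)
  score <- setNames(rep(0, ncol(X)), colnames(X))
  score[names(cnt)] <- as.numeric(cnt)
  r <- rank_desc_stable(colnames(X), unname(score))
  new_ranked_list(r$features, r$scores, "gbdt",
                  meta = list(n_trees = n_trees, seed = seed))
}

#' Run all four rankers
#'
#' @param x A `feature_tbl` restricted to screened features.
#' @param y Class labels.
#' @param seed Integer seed shared (stream-separated) across methods.
#' @param mcfs A [mcfs_params()] for the MCFS ranker.
#' @return Named list of `ranked_list`s (`lasso`, `mrmr`, `mcfs`, `gbdt`).
#' @export
rank_all <- function(x, y, seed = 1L, mcfs = mcfs_params(seed = seed)) {
  list(lasso = rank_lasso(x, y, seed = seed),
       mrmr = rank_mrmr(x, y),
       mcfs = rank_mcfs(x, y, params = mcfs),
       gbdt = rank_gbdt(x, y, seed = seed))
}

#' Write a ranked list as TSV (rank, feature, score) with a meta JSON
#' @param x A `ranked_list`.
#' @param path TSV path; meta goes to `<path>.meta.json`.
#' @export
write_ranked_list <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  jsonlite::write_json(c(list(method = ranking_method(x)), ranking_meta(x)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
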