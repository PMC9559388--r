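#' Stratified fold assignment
#'
#' @param y Class labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @keywords internal
stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  fold <- integer(length(y))
  with_seed(derive_seed(seed, 101L), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

fit_predict_classifier <- function(classifier, X_tr, y_tr, X_te, seed) {
  y_tr <- droplevels(factor(y_tr))
  switch(
    classifier,
    dt = {
      df <- as.data.frame(X_tr)
      df$.y <- y_tr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, cp = 0, xval = 0,
                            maxsurrogate = 0, maxcompete = 0))
      as.character(predict(fit, as.data.frame(X_te), type = "class"))
    },
    rf = {
      fit <- ranger::ranger(x = X_tr, y = y_tr, num.trees = 100,
                            seed = seed, num.threads = 1)
      as.character(predict(fit, X_te, num.threads = 1)$predictions)
    },
    svm = {
      # scale with training statistics; constant columns left untouched
      mu <- colMeans(X_tr)
      sdv <- apply(X_tr, 2, sd)
      sdv[sdv == 0] <- 1
      fit <- e1071::svm(scale(X_tr, mu, sdv), y_tr, kernel = "radial",
                        scale = FALSE)
      as.character(predict(fit, scale(X_te, mu, sdv)))
    },
    abort(paste0("Unknown classifier tag: ", classifier))
  )
}

#' Cross-validated evaluation of a feature prefix
#'
#' Stratified, seeded k-fold cross-validation in which SMOTE balancing is
#' applied to the training part of each fold only; the held-out part is
#' predicted untouched and metrics are pooled over all out-of-fold
#' predictions.
#'
#' @param x A `feature_tbl` (or matrix) containing at least
#'   `prefix_features`.
#' @param y Class labels.
#' @param prefix_features Feature names to use.
#' @param classifier `"dt"`, `"rf"` or `"svm"`.
#' @param folds Number of folds.
#' @param k_smote SMOTE neighbor pool size.
#' @param seed Integer seed (folds, SMOTE and classifier fits).
#' @return A `metrics_report` over the pooled out-of-fold predictions.
#' @export
evaluate_prefix <- function(x, y, prefix_features, classifier = "svm",
                            folds = 10, k_smote = 5, seed = 1L) {
  stopifnot(length(prefix_features) > 0, folds >= 2)
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  stopifnot(all(prefix_features %in% colnames(X)))
  X <- X[, prefix_features, drop = FALSE]
  y <- factor(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    bal <- smote_balance(X[tr, , drop = FALSE], y[tr], k_neighbors = k_smote,
                         seed = derive_seed(seed, 110L) + f)
    pred[te] <- fit_predict_classifier(classifier, bal$x, bal$y,
                                       X[te, , drop = FALSE],
                                       seed = derive_seed(seed, 120L) + f)
  }
  compute_metrics(as.character(y), pred, classes = levels(y))
}

#' Incremental feature selection over a ranked list
#'
#' Evaluates nested prefixes of the ranked list (`step`, `2 * step`, ..., and
#' always the full list) under [evaluate_prefix()], and identifies the
#' smallest prefix attaining the maximum weighted F1 — the optimal
#' classifier. [select_feasible()] additionally finds the smallest prefix
#' within `delta` of that maximum.
#'
#' @param x A `feature_tbl` containing the ranked features.
#' @param y Class labels.
#' @param ranked A `ranked_list`.
#' @param classifier `"dt"`, `"rf"` or `"svm"`.
#' @param step Prefix-size increment.
#' @param folds,k_smote,seed Passed to [evaluate_prefix()].
#' @return An `ifs_result`: tibble of per-prefix metrics with attributes
#'   `method`, `classifier`, `optimal_size`, `optimal_metrics`, `reports`.
#' @export
run_ifs <- function(x, y, ranked, classifier = "svm", step = 5, folds = 10,
                    k_smote = 5, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_list"), step >= 1)
  total <- nrow(ranked)
  if (total == 0) abort("Empty ranked list.")
  sizes <- unique(c(seq(step, total, by = step), total))
  reports <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    reports[[i]] <- evaluate_prefix(x, y, ranked$feature[seq_len(sizes[i])],
                                    classifier = classifier, folds = folds,
                                    k_smote = k_smote, seed = seed)
  }
  rows <- purrr::map2_dfr(sizes, reports, function(sz, r) {
    tibble(prefix_size = sz, acc = r$acc, mcc = r$mcc,
           macro_f1 = r$macro_f1, weighted_f1 = r$weighted_f1)
  })
  best <- which(rows$weighted_f1 == max(rows$weighted_f1))[1]
  structure(rows,
            method = ranking_method(ranked), classifier = classifier,
            optimal_size = sizes[best], optimal_metrics = reports[[best]],
            reports = reports, fold_seed = seed, step = step,
            class = c("ifs_result", class(tibble())))
}

#' @rdname run_ifs
#' @param result An `ifs_result`.
#' @export
optimal_size <- function(result) attr(result, "optimal_size")

#' @rdname run_ifs
#' @export
optimal_metrics <- function(result) attr(result, "optimal_metrics")

#' Smallest prefix within `delta` of the best weighted F1
#'
#' Mirrors the search for a "feasible" classifier: nearly the optimal
#' performance with far fewer features.
#'
#' @param result An `ifs_result`.
#' @param delta Allowed weighted-F1 shortfall from the maximum.
#' @return The feasible prefix size (an integer).
#' @export
select_feasible <- function(result, delta = 0.05) {
  stopifnot(inherits(result, "ifs_result"), nrow(result) > 0, delta >= 0)
  thr <- max(result$weighted_f1) - delta
  min(result$prefix_size[result$weighted_f1 >= thr])
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("<ifs_result> ", attr(x, "method"), " + ", attr(x, "classifier"),
      ": optimal prefix ", optimal_size(x), " (weighted F1 ",
      sprintf("%.4f", max(x$weighted_f1)), ") over ", nrow(x),
      " prefix(es)\n", sep = "")
  NextMethod()
}

#' @export
glance.ifs_result <- function(x, ...) {
  m <- optimal_metrics(x)
  tibble(method = attr(x, "method"), classifier = attr(x, "classifier"),
         optimal_size = optimal_size(x), acc = m$acc, mcc = m$mcc,
         macro_f1 = m$macro_f1, weighted_f1 = m$weighted_f1)
}

#' IFS curve plot
#'
#' Weighted F1 against prefix size, with the optimal prefix highlighted.
#'
#' @param object An `ifs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ifs_result <- function(object, ...) {
  df <- as_tibble(object)
  opt <- optimal_size(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prefix_size,
                                   y = .data$weighted_f1)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = opt, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(
      x = "Number of top-ranked features",
      y = "Weighted F1 (10-fold CV)",
      title = paste0("IFS curve: ", attr(object, "method"), " + ",
                     attr(object, "classifier")),
      subtitle = paste0("Optimal prefix = ", opt)) +
    ggplot2::theme_minimal()
}
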