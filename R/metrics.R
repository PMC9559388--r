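#' Multiclass classification metrics
#'
#' Per-class precision, recall and F1 (`F1 = 2 p r / (p + r)`, with the
#' 0/0 -> 0 convention), overall accuracy, macro and support-weighted F1, and
#' the multiclass Matthews correlation coefficient computed as
#' `cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))` where `X` and `Y` are the one-hot
#' true and predicted label matrices and the covariance is summed over class
#' columns. Weighted F1 is the model-selection objective throughout the
#' package because tumor cohorts are heavily imbalanced.
#'
#' @param y_true,y_pred Equal-length label vectors; `y_pred` values must be
#'   among `classes`.
#' @param classes Class levels (defaults to the union of observed labels).
#' @return A `metrics_report`: list with `per_class` (tibble of class,
#'   precision, recall, f1, support), `acc`, `mcc`, `macro_f1`,
#'   `weighted_f1`.
#' @export
compute_metrics <- function(y_true, y_pred,
                            classes = sort(unique(c(as.character(y_true),
                                                    as.character(y_pred))))) {
  if (length(y_true) == 0) abort("Empty input.")
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!all(y_pred %in% classes) || !all(y_true %in% classes)) {
    abort("Labels outside the declared class set.")
  }
  K <- length(classes)
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- as.numeric(true_n)
  acc <- sum(tp) / length(y_true)
  macro_f1 <- mean(f1)
  weighted_f1 <- sum(support * f1) / sum(support)

  X <- outer(y_true, classes, "==") * 1
  Y <- outer(y_pred, classes, "==") * 1
  cov_sum <- function(A, B) {
    sum(vapply(seq_len(K),
               function(k) stats::cov(A[, k], B[, k]), numeric(1)))
  }
  num <- cov_sum(X, Y)
  den <- sqrt(cov_sum(X, X) * cov_sum(Y, Y))
  mcc <- if (is.na(den) || den == 0) 0 else num / den

  structure(
    list(per_class = tibble(class = classes,
                            precision = as.numeric(precision),
                            recall = as.numeric(recall),
                            f1 = as.numeric(f1),
                            support = support),
         acc = acc, mcc = mcc, macro_f1 = macro_f1,
         weighted_f1 = weighted_f1),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> acc %.4f | mcc %.4f | macro F1 %.4f | weighted F1 %.4f\n",
    x$acc, x$mcc, x$macro_f1, x$weighted_f1))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(acc = x$acc, mcc = x$mcc, macro_f1 = x$macro_f1,
         weighted_f1 = x$weighted_f1)
}
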