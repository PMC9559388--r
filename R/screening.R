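#' Shadow-feature relevance screening
#'
#' Boruta-style all-relevant filtering. Each iteration appends an
#' independently permuted "shadow" copy of every feature, fits a random
#' forest on `[originals | shadows]`, and credits a feature with a hit when
#' its impurity importance exceeds the maximum shadow importance. After every
#' iteration, undecided features whose hit count is binomially more (or less)
#' extreme than chance at level `alpha` — Bonferroni-corrected over the
#' currently undecided features — are accepted (or rejected); whatever
#' survives `max_iter` stays tentative.
#'
#' @param x A `feature_tbl` (or tibble with `sample_id` plus numeric
#'   columns).
#' @param y Class labels, one per row of `x` (factor or character).
#' @param max_iter Maximum screening iterations (>= 10).
#' @param alpha Significance level for the per-feature binomial tests.
#' @param num_trees Trees in the importance forest (per iteration).
#' @param seed Integer seed; the whole run is deterministic in it.
#' @return A `screening_result`: list with `accepted`, `tentative`,
#'   `rejected` (disjoint feature-name vectors partitioning the input),
#'   `hit_counts`, `n_iterations` and `alpha`.
#' @export
boruta_screen <- function(x, y, max_iter = 100, alpha = 0.05,
                          num_trees = 200, seed = 1L) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) {
    abort("Labels must contain at least 2 classes.")
  }
  stopifnot(nrow(X) >= 10, max_iter >= 10)
  feats <- colnames(X)
  d <- length(feats)

  const <- apply(X, 2, function(v) max(v) == min(v))
  rejected <- character(0)
  if (any(const)) {
    warn(paste0(sum(const), " zero-variance feature(s) auto-rejected."))
    rejected <- feats[const]
  }
  active <- feats[!const]
  Xa <- X[, active, drop = FALSE]

  hits <- setNames(integer(length(active)), active)
  status <- setNames(rep("undecided", length(active)), active)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    it_seed <- derive_seed(seed, 60L) + it
    shadows <- with_seed(it_seed, apply(Xa, 2, sample))
    colnames(shadows) <- paste0(".shadow.", active)
    df <- as.data.frame(cbind(Xa, shadows))
    df$.y <- y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = num_trees, importance = "impurity",
                          seed = it_seed, num.threads = 1)
    imp <- fit$variable.importance
    shadow_max <- max(imp[paste0(".shadow.", active)])
    hit_now <- imp[active] > shadow_max
    hits <- hits + as.integer(hit_now)

    und <- names(status)[status == "undecided"]
    if (length(und) == 0) break
    thr <- alpha / length(und)
    p_more <- pbinom(hits[und] - 1, it, 0.5, lower.tail = FALSE)
    p_less <- pbinom(hits[und], it, 0.5)
    status[und[p_more < thr]] <- "accepted"
    status[und[p_less < thr & p_more >= thr]] <- "rejected"
    if (!any(status == "undecided")) break
  }
  status[status == "undecided"] <- "tentative"
  structure(
    list(accepted = names(status)[status == "accepted"],
         tentative = names(status)[status == "tentative"],
         rejected = c(rejected, names(status)[status == "rejected"]),
         hit_counts = hits, n_iterations = n_iter, alpha = alpha),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", length(x$accepted), " accepted / ",
      length(x$tentative), " tentative / ", length(x$rejected),
      " rejected after ", x$n_iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.screening_result <- function(x, ...) {
  feats <- c(x$accepted, x$tentative, x$rejected)
  tibble(feature = feats,
         decision = rep(c("accepted", "tentative", "rejected"),
                        c(length(x$accepted), length(x$tentative),
                          length(x$rejected))),
         hits = unname(x$hit_counts[feats]))
}

#' Features retained by a screening run
#'
#' @param result A `screening_result`.
#' @param include_tentative Keep tentative features too (default drops them:
#'   the screen is a hard cut before ranking).
#' @return Character vector of feature names in input order.
#' @export
screened_features <- function(result, include_tentative = FALSE) {
  keep <- result$accepted
  if (include_tentative) keep <- c(keep, result$tentative)
  ord <- names(result$hit_counts)
  ord[ord %in% keep]
}
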