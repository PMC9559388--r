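#' Extract IF-THEN rules from a decision tree
#'
#' Fits a (seeded, fully grown unless `max_depth` is given) decision tree on
#' all samples restricted to the chosen features, then converts every
#' root-to-leaf path into one rule: an ordered set of
#' `(feature, comparator, threshold)` predicates with comparators `<=` / `>`,
#' a predicted class (the leaf majority), the number of training samples
#' reaching the leaf (`support`), and the fraction of those in the predicted
#' class (`purity`). Repeated predicates on one feature collapse to the
#' tightest interval.
#'
#' @param x A `feature_tbl` (or matrix) containing `optimal_features`.
#' @param y Class labels.
#' @param optimal_features Feature names to restrict the tree to.
#' @param seed Integer seed.
#' @param max_depth Optional depth cap for compact, readable rules.
#' @return A `rule_set`: tibble with columns `rule_id`, `predicted_class`,
#'   `support`, `purity`, `text` and a `predicates` list-column; the fitted
#'   tree and class levels are kept as attributes.
#' @export
extract_rules <- function(x, y, optimal_features, seed = 1L,
                          max_depth = NULL) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  stopifnot(all(optimal_features %in% colnames(X)))
  X <- X[, optimal_features, drop = FALSE]
  y <- factor(y)
  ctrl <- rpart::rpart.control(minsplit = 2, cp = 0, xval = 0,
                               maxsurrogate = 0, maxcompete = 0,
                               maxdepth = max_depth %||% 30)
  df <- as.data.frame(X)
  df$.y <- y
  fit <- with_seed(derive_seed(seed, 131L),
                   rpart::rpart(.y ~ ., data = df, method = "class",
                                control = ctrl))
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  K <- nlevels(y)
  counts <- fr$yval2[, 1 + seq_len(K), drop = FALSE]
  is_leaf <- fr$var == "<leaf>"

  # one primary-split row per internal node, in frame order
  split_row <- integer(nrow(fr))
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  splits <- fit$splits

  rules <- list()
  walk <- function(row, preds) {
    if (is_leaf[row]) {
      cl <- levels(y)[fr$yval[row]]
      supp <- fr$n[row]
      rules[[length(rules) + 1]] <<- list(
        predicates = collapse_predicates(preds),
        predicted_class = cl, support = supp,
        purity = max(counts[row, ]) / supp)
      return(invisible())
    }
    sr <- split_row[row]
    feat <- as.character(fr$var[row])
    thr <- splits[sr, "index"]
    ncat <- splits[sr, "ncat"]
    left <- match(2L * nodes[row], nodes)
    right <- match(2L * nodes[row] + 1L, nodes)
    if (ncat < 0) {  # left branch: x < thr
      walk(left, c(preds, list(list(feat, "<=", thr))))
      walk(right, c(preds, list(list(feat, ">", thr))))
    } else {         # left branch: x >= thr
      walk(left, c(preds, list(list(feat, ">", thr))))
      walk(right, c(preds, list(list(feat, "<=", thr))))
    }
  }
  walk(1L, list())

  tab <- tibble(
    rule_id = seq_along(rules),
    predicted_class = vapply(rules, `[[`, character(1), "predicted_class"),
    support = vapply(rules, function(r) as.integer(r$support), integer(1)),
    purity = vapply(rules, `[[`, numeric(1), "purity"),
    predicates = lapply(rules, `[[`, "predicates"))
  tab$text <- vapply(seq_len(nrow(tab)), function(i) {
    format_rule(tab$predicates[[i]], tab$predicted_class[i])
  }, character(1))
  structure(tab, classes = levels(y), fit = fit,
            class = c("rule_set", class(tibble())))
}

# tightest interval per feature: min over "<=", max over ">"
collapse_predicates <- function(preds) {
  if (length(preds) == 0) {
    return(tibble(feature = character(0), comparator = character(0),
                  threshold = numeric(0)))
  }
  tab <- tibble(feature = vapply(preds, `[[`, character(1), 1),
                comparator = vapply(preds, `[[`, character(1), 2),
                threshold = vapply(preds, `[[`, numeric(1), 3))
  first_seen <- tab |>
    mutate(ord = dplyr::row_number()) |>
    group_by(.data$feature, .data$comparator) |>
    summarise(threshold = ifelse(.data$comparator[1] == "<=",
                                 min(.data$threshold),
                                 max(.data$threshold)),
              ord = min(.data$ord), .groups = "drop") |>
    arrange(.data$ord)
  select(first_seen, -"ord")
}

format_rule <- function(preds, class_label) {
  cond <- if (nrow(preds) == 0) "TRUE" else {
    paste(sprintf("%s %s %.6g", preds$feature, preds$comparator,
                  preds$threshold), collapse = " AND ")
  }
  paste0("IF ", cond, " THEN ", class_label)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> ", nrow(x), " rules over ",
      length(attr(x, "classes")), " classes\n", sep = "")
  NextMethod()
}

#' Predict classes by rule replay
#'
#' Applies each rule's predicates to the rows of `x`; the rules partition
#' the feature space, so each sample matches exactly one rule.
#'
#' @param rules A `rule_set`.
#' @param x A `feature_tbl` or matrix with the rule features.
#' @return Character vector of predicted classes.
#' @export
predict_rules <- function(rules, x) {
  X <- if (inherits(x, "feature_tbl")) feature_matrix(x) else as.matrix(x)
  out <- rep(NA_character_, nrow(X))
  for (i in seq_len(nrow(rules))) {
    p <- rules$predicates[[i]]
    mask <- rep(TRUE, nrow(X))
    for (j in seq_len(nrow(p))) {
      v <- X[, p$feature[j]]
      mask <- mask & if (p$comparator[j] == "<=") v <= p$threshold[j]
                     else v > p$threshold[j]
    }
    out[mask & is.na(out)] <- rules$predicted_class[i]
    # partition property: no sample should match two rules; first match kept
  }
  out
}

#' Rule counts per predicted class
#'
#' @param rules A `rule_set`.
#' @return A tibble of `class` and `n_rules`; classes with no rule count 0.
#' @export
rules_per_class <- function(rules) {
  classes <- attr(rules, "classes")
  cnt <- table(factor(rules$predicted_class, classes))
  tibble(class = classes, n_rules = as.integer(cnt))
}

#' Intersection structure of several feature sets
#'
#' @param named_sets Named list (one element per ranking method) of feature
#'   name vectors.
#' @return An `intersection_report`: list with `membership` (tibble of
#'   feature and the methods containing it), `tiers` (list: k -> features in
#'   exactly k sets) and `core` (features in every set).
#' @export
intersect_feature_sets <- function(named_sets) {
  stopifnot(length(named_sets) >= 2, !is.null(names(named_sets)))
  all_feats <- sort(unique(unlist(named_sets)))
  member <- lapply(all_feats, function(f) {
    names(named_sets)[vapply(named_sets, function(s) f %in% s, logical(1))]
  })
  k <- lengths(member)
  tiers <- split(all_feats, k)
  structure(
    list(membership = tibble(feature = all_feats, methods = member,
                             n_methods = k),
         tiers = tiers,
         core = all_feats[k == length(named_sets)]),
    class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat("<intersection_report> ", nrow(x$membership), " features; core of ",
      length(x$core), "\n", sep = "")
  for (k in rev(names(x$tiers))) {
    cat("  in exactly ", k, " set(s): ", length(x$tiers[[k]]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Feature-type composition of a feature set
#'
#' @param features Feature names.
#' @param feature_types Named type vector (from [feature_types()]).
#' @return Tibble of `type`, `n`, `proportion` over the three tags.
#' @export
feature_type_breakdown <- function(features, feature_types) {
  if (!all(features %in% names(feature_types))) {
    abort("Some features have no type tag.")
  }
  tags <- feature_types[features]
  bad <- setdiff(unique(tags), c("enrichment", "text", "network"))
  if (length(bad) > 0) abort(paste0("Unknown type tag: ", bad[1]))
  cnt <- table(factor(tags, c("enrichment", "text", "network")))
  tibble(type = names(cnt), n = as.integer(cnt),
         proportion = as.numeric(cnt) / max(1, length(features)))
}
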