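# Shared fixtures and independent oracles. Everything is built in code at
# test time; the cache avoids re-simulating the same small cohort per file.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_spec <- function() {
  synthetic_spec(n_genes = 300, n_terms = 20, term_size_range = c(5, 30),
                 n_classes = 3, class_sizes = c(20, 30, 25),
                 drivers_per_class = 2, signal_fraction = 0.6,
                 burden_mean = 25, burden_dispersion = 2, seed = 7)
}

small_world <- function() {
  fixture("small_world", function() {
    spec <- small_spec()
    catalog <- build_annotation_catalog(spec)
    cohort <- simulate_cohort(spec, catalog)
    graph <- build_interaction_graph(spec, catalog)
    list(spec = spec, catalog = catalog, cohort = cohort, graph = graph,
         y = cohort$profiles$class_label,
         enr = encode_enrichment(cohort, catalog))
  })
}

# --- independent oracles ----------------------------------------------------

# hypergeometric upper tail by direct enumeration of the density terms
# (stats::dhyper recurrence; an entirely separate code path from the
# package's log-gamma + log-sum-exp evaluation)
oracle_hyper_tail <- function(N, M, n, m) {
  if (m <= 0) return(1)
  k <- m:min(n, M)
  sum(dhyper(k, M, N - M, n))
}

# multiclass MCC closed form from the confusion matrix
oracle_mcc_confusion <- function(cm) {
  s <- sum(cm)
  c_corr <- sum(diag(cm))
  t_k <- rowSums(cm)  # true counts
  p_k <- colSums(cm)  # predicted counts
  num <- c_corr * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

# expand a confusion matrix into label vectors (row = true, col = predicted)
labels_from_confusion <- function(cm) {
  classes <- paste0("k", seq_len(nrow(cm)))
  yt <- c()
  yp <- c()
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(ncol(cm))) {
      if (cm[i, j] > 0) {
        yt <- c(yt, rep(classes[i], cm[i, j]))
        yp <- c(yp, rep(classes[j], cm[i, j]))
      }
    }
  }
  list(y_true = yt, y_pred = yp, classes = classes)
}

# brute-force greedy mRMR (MID) on 3-state discretized features, written
# from scratch with table()-based mutual information
oracle_mrmr <- function(X, y) {
  disc <- apply(X, 2, function(v) {
    mu <- mean(v); s <- sd(v)
    cut(v, c(-Inf, mu - s, mu + s, Inf), labels = FALSE)
  })
  mi <- function(a, b) {
    jt <- table(a, b) / length(a)
    pa <- rowSums(jt); pb <- colSums(jt)
    tot <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (jt[i, j] > 0) tot <- tot + jt[i, j] * log(jt[i, j] / (pa[i] * pb[j]))
    }
    tot
  }
  d <- ncol(X)
  rel <- sapply(seq_len(d), function(j) mi(disc[, j], y))
  sel <- integer(0)
  for (step in seq_len(d)) {
    rem <- setdiff(seq_len(d), sel)
    crit <- sapply(rem, function(j) {
      if (length(sel) == 0) rel[j]
      else rel[j] - mean(sapply(sel, function(s) mi(disc[, j], disc[, s])))
    })
    sel <- c(sel, rem[which.max(crit)])
  }
  colnames(X)[sel]
}

# class-shifted gaussian design for screening / ranking power checks
make_informative_design <- function(n, n_inf, n_noise, n_classes = 2,
                                    shift = 2, seed = 1) {
  set.seed(seed)
  y <- factor(rep_len(paste0("c", seq_len(n_classes)), n))
  X <- matrix(rnorm(n * (n_inf + n_noise)), n)
  for (j in seq_len(n_inf)) {
    X[, j] <- X[, j] + shift * (as.integer(y) - (n_classes + 1) / 2) /
      max(1, n_classes - 1) * 2
  }
  colnames(X) <- c(sprintf("inf%02d", seq_len(n_inf)),
                   sprintf("noise%02d", seq_len(n_noise)))
  list(x = X, y = y)
}
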