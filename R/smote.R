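#' SMOTE: synthetic minority oversampling
#'
#' Upsamples every class to the majority-class count. Each synthetic sample
#' interpolates a uniformly chosen minority sample `x` toward one of its
#' `k` nearest same-class neighbors `x_nn` (Euclidean metric):
#' `x + u (x_nn - x)` with `u ~ Uniform(0, 1)`, so every synthetic
#' coordinate lies inside the interval spanned by its generating pair.
#' Original samples are retained unchanged. Intended for use on the training
#' part of a fold only — never on held-out data.
#'
#' @param x Numeric matrix or data frame of features (rows = samples).
#' @param y Class labels, one per row.
#' @param k_neighbors Nearest-neighbor pool size; effectively
#'   `min(k_neighbors, class size - 1)`.
#' @param seed Integer seed.
#' @return List with `x` (matrix, originals first) and `y` (factor). The
#'   `"provenance"` attribute records, per synthetic row in order, the
#'   original-row indices of its generating pair and the interpolation
#'   weight `u`.
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 1L) {
  X <- as.matrix(x)
  y <- factor(y)
  sizes <- table(y)
  if (any(sizes < 2)) {
    abort(paste0("Class(es) with a single training sample: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "),
                 ". Repair the stratification before balancing."))
  }
  target <- max(sizes)
  if (all(sizes == target)) return(list(x = X, y = y))
  with_seed(derive_seed(seed, 71L), {
    add_x <- list()
    add_y <- list()
    prov <- list()
    for (cl in names(sizes)[sizes < target]) {
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1, function(r) order(r)[seq_len(k)])
      nn <- matrix(nn, nrow = k)  # k x n_c
      n_new <- target - length(idx)
      base_i <- sample(length(idx), n_new, replace = TRUE)
      nb_i <- vapply(base_i, function(i) nn[sample.int(k, 1), i], integer(1))
      u <- runif(n_new)
      syn <- Xc[base_i, , drop = FALSE] +
        u * (Xc[nb_i, , drop = FALSE] - Xc[base_i, , drop = FALSE])
      add_x[[cl]] <- syn
      add_y[[cl]] <- rep(cl, n_new)
      prov[[cl]] <- tibble(base = idx[base_i], neighbor = idx[nb_i], u = u)
    }
    out <- list(x = rbind(X, do.call(rbind, add_x)),
                y = factor(c(as.character(y), unlist(add_y)),
                           levels = levels(y)))
    # provenance of each synthetic row (original-row indices), in order
    attr(out, "provenance") <- dplyr::bind_rows(prov)
    out
  })
}
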