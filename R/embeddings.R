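#' Build a gene-sentence corpus from a cohort
#'
#' Treats each sample's mutated-gene set as one "sentence" whose tokens are
#' gene identifiers. A gene set has no natural order, so tokens are shuffled
#' uniformly (seeded) per sentence rather than sorted, avoiding artificial
#' alphabetical-window co-occurrence.
#'
#' @param cohort A `cohort`.
#' @param seed Integer seed for the per-sentence shuffles.
#' @return A list of character vectors, one per sample, in cohort order.
#' @export
build_corpus <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort$profiles) > 0)
  with_seed(derive_seed(seed, 41L), {
    lapply(cohort$profiles$genes, function(g) {
      g <- unique(g)
      if (length(g) > 1) sample(g) else g
    })
  })
}

#' Train skip-gram gene embeddings
#'
#' Learns a distributed vector per token with skip-gram plus negative
#' sampling: tokens that share sentences (samples, or random-walk windows)
#' end up near each other in cosine similarity. Training is single-threaded
#' and fully reproducible for a given seed.
#'
#' @param corpus List of character vectors (sentences).
#' @param dim Embedding width. The per-sample text representation defaults to
#'   256 dimensions elsewhere in the package; small widths train much faster
#'   and preserve the co-occurrence geometry needed here.
#' @param window Maximum context window (sampled uniformly up to this).
#' @param epochs Training passes over the corpus.
#' @param min_count Tokens seen fewer times than this are dropped.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linear decay).
#' @param seed Integer seed.
#' @return An `embedding_table`: list with `dim`, `vectors` (token x dim
#'   matrix with rownames) and `training_meta`.
#' @export
train_gene_embeddings <- function(corpus, dim = 256, window = 10,
                                  epochs = 10, min_count = 1,
                                  negative = 5, alpha = 0.025, seed = 1L) {
  stopifnot(length(corpus) > 0, dim >= 1, window >= 1, epochs >= 1)
  tokens <- unlist(corpus, use.names = FALSE)
  cnt <- table(tokens)
  vocab <- names(cnt)[cnt >= min_count]
  if (length(vocab) == 0) {
    abort("No token reaches `min_count`; vocabulary is empty.",
          class = "tumorsig_config_error")
  }
  vmap <- setNames(seq_along(vocab), vocab)
  enc <- lapply(corpus, function(s) unname(vmap[s[s %in% vocab]]))
  enc <- enc[lengths(enc) > 0]
  vecs <- sgns_train_cpp(enc, length(vocab),
                         as.numeric(cnt[vocab]), as.integer(dim),
                         as.integer(window), as.integer(epochs),
                         as.integer(negative), alpha,
                         as.numeric(derive_seed(seed, 43L)))
  rownames(vecs) <- vocab
  structure(list(dim = as.integer(dim), vectors = vecs,
                 training_meta = list(window = window, epochs = epochs,
                                      min_count = min_count,
                                      negative = negative, seed = seed)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " tokens x ", x$dim,
      " dims\n", sep = "")
  invisible(x)
}

#' @export
tidy.embedding_table <- function(x, ...) {
  tab <- as_tibble(as.data.frame(x$vectors))
  names(tab) <- sprintf("v%03d", seq_len(x$dim) - 1)
  dplyr::bind_cols(tibble(token = rownames(x$vectors)), tab)
}

#' Cosine similarity between two embedded tokens
#' @param table An `embedding_table`.
#' @param a,b Token identifiers.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
embedding_cosine <- function(table, a, b) {
  va <- table$vectors[a, ]
  vb <- table$vectors[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# mean-vector aggregation shared by the text and network encoders
aggregate_embeddings <- function(cohort, table, prefix, type) {
  stopifnot(inherits(cohort, "cohort"), inherits(table, "embedding_table"))
  vocab <- rownames(table$vectors)
  mats <- t(vapply(cohort$profiles$genes, function(g) {
    g <- intersect(unique(g), vocab)
    if (length(g) == 0) return(rep(0, table$dim))
    colMeans(table$vectors[g, , drop = FALSE])
  }, numeric(table$dim)))
  n_absent <- sum(vapply(cohort$profiles$genes,
                         function(g) !any(unique(g) %in% vocab), logical(1)))
  if (n_absent > 0) {
    warn(paste0(n_absent, " sample(s) have no genes in the embedding ",
                "vocabulary; their rows are zero vectors."))
  }
  feats <- sprintf("%s_%03d", prefix, seq_len(table$dim) - 1)
  colnames(mats) <- feats
  out <- dplyr::bind_cols(tibble(sample_id = cohort$profiles$sample_id),
                          as_tibble(as.data.frame(mats)))
  new_feature_tbl(out, setNames(rep(type, length(feats)), feats))
}

#' Per-sample text features: mean of member-gene embedding vectors
#'
#' @param cohort A `cohort`.
#' @param table An `embedding_table` from [train_gene_embeddings()].
#' @return A `feature_tbl` with columns `txt_000` ... tagged `"text"`.
#'   Samples with no embedded genes get a zero row (with a warning).
#' @export
embed_samples_text <- function(cohort, table) {
  aggregate_embeddings(cohort, table, "txt", "text")
}

#' Write / read an embedding table as TSV
#' @param table An `embedding_table`.
#' @param path File path.
#' @export
write_embeddings <- function(table, path) {
  readr::write_tsv(tidy.embedding_table(table), path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(token = "c",
                                                       .default = "d"))
  vecs <- as.matrix(tab[, -1])
  rownames(vecs) <- tab$token
  structure(list(dim = ncol(vecs), vectors = vecs,
                 training_meta = list()),
            class = "embedding_table")
}
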