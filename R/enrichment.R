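#' Log-10 hypergeometric upper-tail probability
#'
#' Computes `log10 P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: the chance
#' that a random draw of `n` genes from a universe of `N` containing a gene
#' set of size `M` hits that set at least `m` times. The tail is evaluated
#' entirely in log space (log-gamma terms combined by log-sum-exp), so no
#' intermediate quantity underflows even for extreme overlaps.
#'
#' @param N Universe size(s).
#' @param M Gene-set size(s), `0 <= M <= N`.
#' @param n Sample (query-set) size(s), `0 <= n <= N`.
#' @param m Observed overlap(s), `0 <= m <= min(n, M)`.
#' @return Numeric vector of log10 tail probabilities (all `<= 0`;
#'   `m = 0` gives exactly `0`).
#' @export
#' @examples
#' log10_hypergeom_tail(20, 5, 4, 2)  # log10(1205/4845)
log10_hypergeom_tail <- function(N, M, n, m) {
  args <- vctrs_recycle(N = N, M = M, n = n, m = m)
  with(args, {
    check_count <- function(v, nm) {
      if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
        abort(paste0("`", nm, "` must be a nonnegative integer."),
              class = "tumorsig_domain_error")
      }
    }
    check_count(N, "N"); check_count(M, "M")
    check_count(n, "n"); check_count(m, "m")
    if (any(M > N)) abort("`M` must not exceed `N`.",
                          class = "tumorsig_domain_error")
    if (any(n > N)) abort("`n` must not exceed `N`.",
                          class = "tumorsig_domain_error")
    if (any(m > pmin(n, M))) abort("`m` must not exceed min(n, M).",
                                   class = "tumorsig_domain_error")
    log10_hypergeom_tail_cpp(as.integer(N), as.integer(M),
                             as.integer(n), as.integer(m))
  })
}

# base-R recycling helper (common length, error on incompatibility)
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  bad <- lengths(xs) != len & lengths(xs) != 1
  if (any(bad)) abort("Arguments must have length 1 or a common length.")
  lapply(xs, rep_len, len)
}

#' Per-sample gene-set enrichment score
#'
#' The enrichment score of a sample against a term is
#' `-log10 P(X >= m)` where `m` is the overlap between the sample's mutated
#' genes (restricted to the catalog universe) and the term's gene set: a
#' larger score means the sample's mutations hit the term more than chance
#' drawing would. Scores are capped at `score_cap`, and an overlap of zero
#' scores exactly 0.
#'
#' @param profile A character vector of mutated genes, or a list/one-row
#'   tibble with a `genes` element.
#' @param term_id Term identifier present in `catalog`.
#' @param catalog An `annotation_catalog`.
#' @param score_cap Upper bound on the score (default 300, i.e. p ~ 1e-300).
#' @return A single nonnegative score.
#' @export
enrichment_score <- function(profile, term_id, catalog, score_cap = 300) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (!term_id %in% names(catalog$terms)) {
    abort(paste0("Unknown term id: ", term_id),
          class = "tumorsig_lookup_error")
  }
  genes <- if (is.character(profile)) profile else profile$genes
  if (is.list(genes)) genes <- genes[[1]]
  g <- intersect(unique(genes), catalog$universe)
  n <- length(g)
  if (n == 0) {
    warn("Sample has no genes inside the catalog universe; score is 0.")
    return(0)
  }
  term <- catalog$terms[[term_id]]
  m <- length(intersect(g, term))
  if (m == 0) return(0)
  min(-log10_hypergeom_tail(length(catalog$universe), length(term), n, m),
      score_cap)
}

#' Encode a cohort as an enrichment feature table
#'
#' Scores every sample against every catalog term (column order follows the
#' catalog). Overlap counts are obtained in one sparse matrix product, then
#' converted to capped `-log10` tail probabilities.
#'
#' @param cohort A `cohort` sharing the catalog's universe.
#' @param catalog An `annotation_catalog`.
#' @param score_cap Upper bound on scores (default 300).
#' @return A `feature_tbl` of shape samples x terms, all tagged
#'   `"enrichment"`.
#' @export
encode_enrichment <- function(cohort, catalog, score_cap = 300) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(catalog, "annotation_catalog"))
  universe <- catalog$universe
  N <- length(universe)
  gidx <- setNames(seq_len(N), universe)
  profiles <- cohort$profiles
  P <- nrow(profiles)
  term_ids <- names(catalog$terms)
  Tn <- length(term_ids)

  # sample x gene incidence (in-universe genes only)
  per_sample <- lapply(profiles$genes,
                       function(g) unname(gidx[intersect(unique(g),
                                                         universe)]))
  n_in <- lengths(per_sample)
  if (any(n_in == 0)) {
    warn(paste0(sum(n_in == 0),
                " sample(s) have no genes inside the universe; ",
                "their scores are all 0."))
  }
  S <- Matrix::sparseMatrix(
    i = rep.int(seq_len(P), n_in),
    j = unlist(per_sample),
    x = 1, dims = c(P, N))
  G <- Matrix::sparseMatrix(
    i = unname(unlist(lapply(catalog$terms, function(g) gidx[g]))),
    j = rep.int(seq_len(Tn), lengths(catalog$terms)),
    x = 1, dims = c(N, Tn))
  m_mat <- as.matrix(S %*% G)  # overlap counts, P x T

  M_vec <- lengths(catalog$terms)
  scores <- matrix(0, P, Tn)
  nz <- which(m_mat > 0)
  if (length(nz) > 0) {
    rowi <- (nz - 1) %% P + 1
    coli <- (nz - 1) %/% P + 1
    scores[nz] <- pmin(
      -log10_hypergeom_tail(N, M_vec[coli], n_in[rowi], m_mat[nz]),
      score_cap)
  }
  colnames(scores) <- term_ids
  out <- as_tibble(as.data.frame(scores, check.names = FALSE))
  out <- dplyr::bind_cols(tibble(sample_id = profiles$sample_id), out)
  new_feature_tbl(out, setNames(rep("enrichment", Tn), term_ids))
}
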