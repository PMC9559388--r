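#' Feature tables
#'
#' Per-sample feature matrices are carried as tibbles whose first column is
#' `sample_id`, with one numeric column per feature and a `feature_types`
#' attribute tagging every feature as `"enrichment"`, `"text"` or
#' `"network"`.
#'
#' @param x A tibble with a `sample_id` column and numeric feature columns.
#' @param types Named character vector, one tag per feature column.
#' @return A `feature_tbl`.
#' @export
new_feature_tbl <- function(x, types) {
  stopifnot(is.data.frame(x), names(x)[1] == "sample_id")
  feats <- setdiff(names(x), "sample_id")
  stopifnot(!anyDuplicated(feats), all(feats %in% names(types)))
  if (anyNA(x)) abort("Feature tables must not contain missing values.")
  types <- types[feats]
  bad <- setdiff(unique(types), c("enrichment", "text", "network"))
  if (length(bad) > 0) {
    abort(paste0("Unknown feature type tag: ", paste(bad, collapse = ", ")))
  }
  structure(as_tibble(x), feature_types = types,
            class = c("feature_tbl", class(as_tibble(x))))
}

#' @rdname new_feature_tbl
#' @export
feature_types <- function(x) attr(x, "feature_types")

#' @rdname new_feature_tbl
#' @export
feature_names <- function(x) setdiff(names(x), "sample_id")

# numeric matrix view (rownames = sample ids)
feature_matrix <- function(x) {
  m <- as.matrix(x[, feature_names(x), drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' Combine feature tables column-wise
#'
#' Joins several `feature_tbl`s on `sample_id` (all must cover the same
#' samples in the same order) and concatenates their type tags.
#'
#' @param ... `feature_tbl` objects.
#' @return A `feature_tbl`.
#' @export
bind_feature_sets <- function(...) {
  tbls <- list(...)
  stopifnot(length(tbls) >= 1)
  ids <- tbls[[1]]$sample_id
  for (t in tbls) stopifnot(identical(t$sample_id, ids))
  out <- do.call(cbind, c(list(tbls[[1]]),
                          lapply(tbls[-1], function(t) t[, feature_names(t),
                                                         drop = FALSE])))
  types <- do.call(c, lapply(tbls, feature_types))
  new_feature_tbl(as_tibble(out), types)
}

#' Write / read a feature table as TSV plus a sidecar JSON of type tags
#'
#' @param x A `feature_tbl`.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.types.json`.
#' @export
write_features <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  jsonlite::write_json(as.list(feature_types(x)),
                       paste0(path, ".types.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"))
  types <- unlist(jsonlite::read_json(paste0(path, ".types.json")))
  new_feature_tbl(tab, types)
}
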