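#' Specify a synthetic mutation cohort
#'
#' Bundles every knob of the synthetic-data generator: a gene universe, a
#' catalog of gene sets ("terms"), class-specific driver terms, per-sample
#' mutation burden, and a gene-interaction graph whose communities align with
#' the terms. The defaults describe the standard validation cohort used
#' throughout the package: 6 tumor classes over 600 samples (imbalanced, as
#' real tumor cohorts are), 2000 genes, 150 terms, and half of each sample's
#' mutations drawn from its class's driver pathways.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_terms Number of gene sets in the annotation catalog.
#' @param term_size_range Length-2 integer vector, inclusive bounds on the
#'   number of genes per term.
#' @param n_classes Number of tumor classes.
#' @param drivers_per_class Number of driver terms planted per class.
#' @param class_sizes Integer vector of per-class sample counts
#'   (length `n_classes`, each at least 2).
#' @param signal_fraction Probability that a single mutation draw comes from
#'   the class's driver-term gene union rather than the whole universe.
#' @param burden_mean,burden_dispersion Mean and dispersion (negative-binomial
#'   `size`) of the per-sample mutation count, floored at 3.
#' @param edge_prob_within_term,edge_prob_background Edge probabilities for
#'   gene pairs sharing a term versus all other pairs.
#' @param seed Integer seed; all generator functions are deterministic in it.
#'
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_genes = 200, n_terms = 10, n_classes = 2,
#'                        class_sizes = c(20, 30), seed = 1)
synthetic_spec <- function(n_genes = 2000,
                           n_terms = 150,
                           term_size_range = c(10, 200),
                           n_classes = 6,
                           drivers_per_class = 3,
                           class_sizes = c(60, 160, 130, 80, 120, 50),
                           signal_fraction = 0.5,
                           burden_mean = 30,
                           burden_dispersion = 1.5,
                           edge_prob_within_term = 0.3,
                           edge_prob_background = 0.002,
                           seed = 1L) {
  term_size_range <- as.integer(term_size_range)
  stopifnot(length(term_size_range) == 2, term_size_range[1] >= 1)
  if (term_size_range[2] > n_genes) {
    abort("`term_size_range` maximum exceeds `n_genes`.",
          class = "tumorsig_invalid_spec")
  }
  if (drivers_per_class > n_terms) {
    abort("`drivers_per_class` exceeds `n_terms`.",
          class = "tumorsig_invalid_spec")
  }
  if (length(class_sizes) != n_classes || any(class_sizes < 2)) {
    abort("`class_sizes` must have length `n_classes` with all sizes >= 2.",
          class = "tumorsig_invalid_spec")
  }
  if (signal_fraction < 0 || signal_fraction > 1) {
    abort("`signal_fraction` must lie in [0, 1].",
          class = "tumorsig_invalid_spec")
  }
  stopifnot(burden_mean > 0, burden_dispersion > 0,
            edge_prob_within_term >= 0, edge_prob_within_term <= 1,
            edge_prob_background >= 0, edge_prob_background <= 1)
  structure(
    list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
         term_size_range = term_size_range, n_classes = as.integer(n_classes),
         drivers_per_class = as.integer(drivers_per_class),
         class_sizes = as.integer(class_sizes),
         signal_fraction = signal_fraction, burden_mean = burden_mean,
         burden_dispersion = burden_dispersion,
         edge_prob_within_term = edge_prob_within_term,
         edge_prob_background = edge_prob_background,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_classes, " classes / ",
      sum(x$class_sizes), " samples, ", x$n_genes, " genes, ",
      x$n_terms, " terms, signal_fraction = ", x$signal_fraction,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

gene_universe <- function(n_genes) sprintf("G%06d", seq_len(n_genes))

# sample() treats a length-1 numeric vector as 1:x; this never does
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Build a synthetic annotation catalog
#'
#' Draws `n_terms` gene sets over the spec's universe, each a
#' without-replacement sample of a size uniform on `term_size_range`.
#' Roughly 80% of terms are tagged as GO-like and 20% as KEGG-like, mirroring
#' the composition of real functional catalogs; the tag has no effect on
#' scoring, which treats all terms identically.
#'
#' @param spec A [synthetic_spec()].
#' @return An `annotation_catalog`: a list with `universe` (ordered gene
#'   identifiers), `terms` (named list of gene-identifier vectors) and
#'   `namespace` (named vector, `"GO"` or `"KEGG"` per term).
#' @export
build_annotation_catalog <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  universe <- gene_universe(spec$n_genes)
  with_seed(derive_seed(spec$seed, 11L), {
    sizes <- resample(seq(spec$term_size_range[1], spec$term_size_range[2]),
                      spec$n_terms, replace = TRUE)
    ns <- ifelse(runif(spec$n_terms) < 0.8, "GO", "KEGG")
    ids <- ifelse(ns == "GO",
                  sprintf("GO%06d", seq_len(spec$n_terms)),
                  sprintf("hsa%05d", seq_len(spec$n_terms)))
    terms <- lapply(sizes, function(s) sample(universe, s))
    names(terms) <- ids
    new_annotation_catalog(universe, terms, setNames(ns, ids))
  })
}

new_annotation_catalog <- function(universe, terms, namespace = NULL) {
  stopifnot(length(terms) > 0, !is.null(names(terms)),
            !anyDuplicated(names(terms)))
  ok <- vapply(terms, function(g) length(g) > 0 && all(g %in% universe),
               logical(1))
  if (!all(ok)) {
    abort("Every term must be nonempty and a subset of the universe.",
          class = "tumorsig_invalid_catalog")
  }
  if (is.null(namespace)) {
    namespace <- setNames(rep("GO", length(terms)), names(terms))
  }
  structure(list(universe = universe, terms = terms, namespace = namespace),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("<annotation_catalog> ", length(x$terms), " terms over ",
      length(x$universe), " genes (",
      sum(x$namespace == "GO"), " GO-like, ",
      sum(x$namespace == "KEGG"), " KEGG-like)\n", sep = "")
  invisible(x)
}

#' @export
tidy.annotation_catalog <- function(x, ...) {
  tibble(term_id = names(x$terms),
         namespace = unname(x$namespace[names(x$terms)]),
         size = lengths(x$terms),
         genes = unname(x$terms))
}

#' Simulate a mutation cohort with planted driver pathways
#'
#' Each class is assigned `drivers_per_class` driver terms (without
#' replacement across classes whenever the catalog is large enough, so the
#' ground truth is unambiguous). A sample's mutation count is negative
#' binomial (floored at 3); each mutation falls in the class's driver-gene
#' union with probability `signal_fraction`, otherwise anywhere in the
#' universe, and duplicate gene draws collapse to a set.
#'
#' @param spec A [synthetic_spec()].
#' @param catalog The [build_annotation_catalog()] output for the same spec.
#' @return A `cohort`: list with `profiles` (tibble of `sample_id`,
#'   `class_label` and a `genes` list-column), `universe`, `classes`, and
#'   `truth` (named list class -> driver term ids).
#' @export
simulate_cohort <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(catalog, "annotation_catalog"))
  if (!identical(catalog$universe, gene_universe(spec$n_genes))) {
    abort("`catalog` was not built over this spec's universe.",
          class = "tumorsig_invalid_spec")
  }
  universe <- catalog$universe
  classes <- sprintf("C%d", seq_len(spec$n_classes))
  with_seed(derive_seed(spec$seed, 23L), {
    term_ids <- names(catalog$terms)
    need <- spec$drivers_per_class * spec$n_classes
    if (need <= spec$n_terms) {
      picked <- resample(term_ids, need)
    } else {
      picked <- unlist(lapply(seq_len(spec$n_classes), function(i) {
        resample(term_ids, spec$drivers_per_class)
      }))
    }
    truth <- split(picked, rep(classes, each = spec$drivers_per_class))
    truth <- truth[classes]

    profiles <- vector("list", spec$n_classes)
    sample_no <- 0L
    for (k in seq_len(spec$n_classes)) {
      union_k <- unique(unlist(catalog$terms[truth[[k]]], use.names = FALSE))
      if (length(union_k) == 0) {
        abort("Driver gene union is empty.", class = "tumorsig_invalid_spec")
      }
      n_k <- spec$class_sizes[k]
      genes_k <- vector("list", n_k)
      counts <- pmax(3L, rnbinom(n_k, mu = spec$burden_mean,
                                 size = spec$burden_dispersion))
      for (i in seq_len(n_k)) {
        from_driver <- runif(counts[i]) < spec$signal_fraction
        g <- character(counts[i])
        if (any(from_driver)) {
          g[from_driver] <- resample(union_k, sum(from_driver),
                                     replace = TRUE)
        }
        if (any(!from_driver)) {
          g[!from_driver] <- sample(universe, sum(!from_driver),
                                    replace = TRUE)
        }
        genes_k[[i]] <- sort(unique(g))
      }
      profiles[[k]] <- tibble(
        sample_id = sprintf("S%04d", sample_no + seq_len(n_k)),
        class_label = classes[k],
        genes = genes_k)
      sample_no <- sample_no + n_k
    }
    new_cohort(bind_rows(profiles), universe, classes, truth)
  })
}

new_cohort <- function(profiles, universe, classes, truth = NULL) {
  stopifnot(!anyDuplicated(profiles$sample_id),
            all(profiles$class_label %in% classes))
  structure(list(profiles = profiles, universe = universe,
                 classes = classes, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$profiles), " samples, ",
      length(x$classes), " classes, ", length(x$universe),
      " genes in universe\n", sep = "")
  print(count(x$profiles, .data$class_label))
  invisible(x)
}

#' @export
tidy.cohort <- function(x, ...) {
  tidyr::unnest(x$profiles, "genes") |>
    dplyr::rename(gene = "genes")
}

#' Build a synthetic weighted gene-interaction graph
#'
#' Produces an undirected graph over the spec's universe in which gene pairs
#' sharing at least one catalog term are connected with probability
#' `edge_prob_within_term` and all other pairs with probability
#' `edge_prob_background`, so graph communities align with gene sets — the
#' structure a confidence-weighted protein-interaction network has around
#' pathways. Edge confidences are Beta(2, 2) rescaled to (0.15, 0.999].
#'
#' @param spec A [synthetic_spec()].
#' @param catalog The matching [build_annotation_catalog()] output.
#' @return An [igraph::graph] with a `weight` edge attribute and one vertex
#'   per universe gene (isolated genes included).
#' @export
build_interaction_graph <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(catalog, "annotation_catalog"))
  n <- spec$n_genes
  universe <- catalog$universe
  with_seed(derive_seed(spec$seed, 37L), {
    idx <- setNames(seq_len(n), universe)
    within <- lapply(catalog$terms, function(g) {
      i <- sort(idx[g])
      if (length(i) < 2) return(NULL)
      pr <- utils::combn(i, 2L)
      pr[1, ] + (pr[2, ] - 1) * n  # pair key, i < j
    })
    within_keys <- unique(unlist(within, use.names = FALSE))
    keep_w <- within_keys[runif(length(within_keys)) <
                            spec$edge_prob_within_term]

    n_pairs <- n * (n - 1) / 2
    n_bg <- rbinom(1L, n_pairs, spec$edge_prob_background)
    bg_lin <- sample(n_pairs, n_bg)
    # decode linear index over pairs (i < j), row-wise upper triangle
    j_bg <- ceiling((1 + sqrt(1 + 8 * bg_lin)) / 2)
    i_bg <- bg_lin - (j_bg - 1) * (j_bg - 2) / 2
    bg_keys <- i_bg + (j_bg - 1) * n
    bg_keys <- setdiff(bg_keys, within_keys)

    keys <- c(keep_w, bg_keys)
    jj <- (keys - 1) %/% n + 1
    ii <- keys - (jj - 1) * n
    w <- 0.15 + rbeta(length(keys), 2, 2) * (0.999 - 0.15)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = universe)
    if (length(keys) > 0) {
      g <- igraph::add_edges(g, rbind(ii, jj), weight = w)
    }
    g
  })
}

#' Write / read cohort, catalog, graph and truth files
#'
#' Plain-text interchange: the cohort as a MAF-lite TSV (`sample_id`, `class`,
#' `gene`; one row per sample-gene pair), the catalog as GMT, the graph as a
#' 3-column edge list, and the driver truth map as JSON.
#'
#' @param cohort A `cohort`.
#' @param catalog An `annotation_catalog`.
#' @param graph An igraph with `weight` edge attribute.
#' @param path Output (or input) file path.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
write_cohort <- function(cohort, path) {
  tab <- tidy.cohort(cohort)
  names(tab) <- c("sample_id", "class", "gene")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname cohort-io
#' @param universe Gene universe to declare when reading; defaults to the
#'   genes observed in the file.
#' @export
read_cohort <- function(path, universe = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("sample_id", "class", "gene") %in% names(tab)))
  if (is.null(universe)) universe <- sort(unique(tab$gene))
  prof <- tab |>
    group_by(.data$sample_id) |>
    summarise(class_label = .data$class[1],
              genes = list(sort(unique(.data$gene))), .groups = "drop")
  # preserve file order of first appearance
  prof <- prof[match(unique(tab$sample_id), prof$sample_id), ]
  new_cohort(prof, universe, unique(prof$class_label))
}

#' @rdname cohort-io
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$terms), function(id) {
    paste(c(id, catalog$namespace[[id]], catalog$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cohort-io
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  ns <- vapply(parts, `[[`, character(1), 2)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(terms)))
  ns[!ns %in% c("GO", "KEGG")] <- "GO"
  new_annotation_catalog(universe, terms, setNames(ns, ids))
}

#' @rdname cohort-io
#' @export
write_edges <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:3] <- c("gene_a", "gene_b", "weight")
  readr::write_tsv(as_tibble(el), path)
  invisible(path)
}

#' @rdname cohort-io
#' @param nodes Optional vertex names to include even when isolated.
#' @export
read_edges <- function(path, nodes = NULL) {
  el <- readr::read_tsv(path, col_types = "ccd")
  verts <- unique(c(nodes, el$gene_a, el$gene_b))
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' @rdname cohort-io
#' @export
write_truth <- function(cohort, path) {
  jsonlite::write_json(cohort$truth, path, auto_unbox = FALSE)
  invisible(path)
}
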