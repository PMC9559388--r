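#' Run the full mutation-profile classification pipeline
#'
#' Chains every stage on a synthetic cohort: simulate (cohort, catalog,
#' interaction graph) -> encode (enrichment, text, network features) ->
#' shadow-feature screening -> four-way ranking -> incremental feature
#' selection per classifier -> feasible-prefix intersection -> decision-tree
#' rule extraction. Embedding widths default to 32, which preserves the
#' co-occurrence geometry at a fraction of the cost of the full 256/500-wide
#' representations.
#'
#' @param spec A [synthetic_spec()].
#' @param text_dim,network_dim Embedding widths for the text and network
#'   encoders.
#' @param text_epochs,net_epochs Skip-gram epochs per encoder.
#' @param walk_length,walks_per_node Random-walk parameters.
#' @param screen_max_iter,screen_alpha Screening parameters.
#' @param ifs_step IFS prefix-size increment.
#' @param folds Cross-validation folds.
#' @param classifiers Subset of `c("dt", "rf", "svm")` to run IFS with.
#' @param delta Feasible-prefix tolerance on weighted F1.
#' @param seed Integer seed for every downstream stage (the generator uses
#'   `spec$seed`).
#' @param verbose Print per-stage progress.
#' @return A `tumorsig_pipeline` list: the simulated objects, feature table,
#'   screening result, rankings, IFS results (`ifs[[method]][[classifier]]`),
#'   feasible sizes, intersection report, per-method rule sets, and summary
#'   tibbles.
#' @export
run_pipeline <- function(spec = synthetic_spec(),
                         text_dim = 32, network_dim = 32,
                         text_epochs = 10, net_epochs = 5,
                         walk_length = 80, walks_per_node = 10,
                         screen_max_iter = 50, screen_alpha = 0.05,
                         ifs_step = 10, folds = 10,
                         classifiers = c("dt", "svm"),
                         delta = 0.05, seed = spec$seed,
                         verbose = interactive()) {
  say <- function(...) if (verbose) message(...)

  say("simulating cohort ...")
  catalog <- build_annotation_catalog(spec)
  cohort <- simulate_cohort(spec, catalog)
  graph <- build_interaction_graph(spec, catalog)
  y <- cohort$profiles$class_label

  say("encoding enrichment features ...")
  enr <- encode_enrichment(cohort, catalog)

  say("encoding text features ...")
  corpus <- build_corpus(cohort, seed = seed)
  txt_table <- train_gene_embeddings(corpus, dim = text_dim,
                                     epochs = text_epochs, seed = seed)
  txt <- embed_samples_text(cohort, txt_table)

  say("encoding network features ...")
  walks <- generate_walks(graph, walk_length = walk_length,
                          walks_per_node = walks_per_node, seed = seed)
  net_table <- train_node_embeddings(walks, dim = network_dim,
                                     epochs = net_epochs, seed = seed)
  net <- embed_samples_network(cohort, net_table)

  features <- bind_feature_sets(enr, txt, net)

  say("screening ", length(feature_names(features)), " features ...")
  screening <- boruta_screen(features, y, max_iter = screen_max_iter,
                             alpha = screen_alpha, seed = seed)
  kept <- screened_features(screening)
  if (length(kept) < 2) {
    abort("Fewer than 2 features survive screening; nothing to rank.")
  }
  x_kept <- features[, c("sample_id", kept)]
  x_kept <- new_feature_tbl(x_kept, feature_types(features)[kept])

  say("ranking ", length(kept), " screened features 4 ways ...")
  rankings <- rank_all(x_kept, y, seed = seed)

  say("incremental feature selection ...")
  ifs <- lapply(rankings, function(rl) {
    res <- lapply(classifiers, function(clf) {
      run_ifs(x_kept, y, rl, classifier = clf, step = ifs_step,
              folds = folds, seed = seed)
    })
    names(res) <- classifiers
    res
  })

  feas_clf <- if ("svm" %in% classifiers) "svm" else classifiers[1]
  feasible_sizes <- vapply(ifs, function(per_clf) {
    select_feasible(per_clf[[feas_clf]], delta = delta)
  }, numeric(1))
  feasible_sets <- lapply(names(rankings), function(m) {
    rankings[[m]]$feature[seq_len(feasible_sizes[[m]])]
  })
  names(feasible_sets) <- names(rankings)
  intersection <- intersect_feature_sets(feasible_sets)

  rules <- NULL
  if ("dt" %in% classifiers) {
    say("extracting decision rules ...")
    rules <- lapply(names(rankings), function(m) {
      n_opt <- optimal_size(ifs[[m]][["dt"]])
      extract_rules(x_kept, y, rankings[[m]]$feature[seq_len(n_opt)],
                    seed = seed)
    })
    names(rules) <- names(rankings)
  }

  summary_tbl <- bind_rows(lapply(ifs, function(per_clf) {
    bind_rows(lapply(per_clf, glance))
  }))

  structure(
    list(spec = spec, catalog = catalog, cohort = cohort, graph = graph,
         features = features, screening = screening,
         screened = kept, rankings = rankings, ifs = ifs,
         feasible_sizes = feasible_sizes, feasible_sets = feasible_sets,
         intersection = intersection, rules = rules,
         breakdown = feature_type_breakdown(kept, feature_types(features)),
         summary = summary_tbl, seed = seed),
    class = "tumorsig_pipeline")
}

#' @export
print.tumorsig_pipeline <- function(x, ...) {
  cat("<tumorsig_pipeline> ", nrow(x$cohort$profiles), " samples, ",
      length(feature_names(x$features)), " features -> ",
      length(x$screened), " screened\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
glance.tumorsig_pipeline <- function(x, ...) x$summary

#' Median normalized rank of planted driver features per ranked list
#'
#' For each ranking method, finds the positions of the cohort's driver-term
#' enrichment features and reports their median rank divided by the list
#' length — a recovery measure (small is good).
#'
#' @param pipeline A `tumorsig_pipeline`.
#' @param n_total Denominator for the rank fraction. The default is the
#'   number of encoded features: screening-rejected features rank below
#'   every list member by the screen's own verdict, so a ranked list is the
#'   head of an importance ordering over the whole feature space.
#' @return Tibble of `method`, `n_found`, `median_rank_fraction`.
#' @export
driver_rank_recovery <- function(pipeline,
                                 n_total = length(
                                   feature_names(pipeline$features))) {
  drivers <- unique(unlist(pipeline$cohort$truth))
  bind_rows(lapply(names(pipeline$rankings), function(m) {
    rl <- pipeline$rankings[[m]]
    pos <- match(drivers, rl$feature)
    tibble(method = m,
           n_found = sum(!is.na(pos)),
           median_rank_fraction = stats::median(pos, na.rm = TRUE) /
             n_total)
  }))
}
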