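#' Second-order biased random walks on a weighted graph
#'
#' Generates `walks_per_node` walks from every node. The first step from a
#' source is drawn proportional to edge weight; afterwards the step from `v`
#' with predecessor `t` is proportional to `alpha(t, x) * w(v, x)` with
#' `alpha = 1/p` for returning to `t`, `1` for nodes adjacent to `t`, and
#' `1/q` otherwise — small `q` pushes walks outward, small `p` keeps them
#' local. Isolated nodes yield length-1 walks.
#'
#' @param graph An [igraph::graph] with a `weight` edge attribute (all
#'   weights strictly positive) and named vertices.
#' @param p Return parameter (> 0).
#' @param q In-out parameter (> 0).
#' @param walk_length Maximum walk length (nodes, including the source).
#' @param walks_per_node Walks started per node.
#' @param seed Integer seed.
#' @return List of character vectors of vertex names, length
#'   `vcount(graph) * walks_per_node`.
#' @export
generate_walks <- function(graph, p = 1, q = 1, walk_length = 80,
                           walks_per_node = 10, seed = 1L) {
  stopifnot(igraph::vcount(graph) > 0, p > 0, q > 0,
            walk_length >= 1, walks_per_node >= 1)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  stopifnot(all(w > 0))
  names <- igraph::V(graph)$name
  el <- igraph::as_edgelist(graph, names = FALSE)
  # symmetric CSR adjacency, neighbors sorted within each node
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  ww <- c(w, w)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; ww <- ww[o]
  n <- igraph::vcount(graph)
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  walks <- generate_walks_cpp(as.integer(ptr), as.integer(to - 1L), ww,
                              n, p, q, as.integer(walk_length),
                              as.integer(walks_per_node),
                              as.numeric(derive_seed(seed, 53L)))
  lapply(walks, function(iv) names[iv])
}

#' Train node embeddings on random walks
#'
#' Feeds the walks to the same skip-gram trainer used for gene sentences:
#' nodes are words, walks are sentences. Nodes in dense, well-connected
#' neighborhoods (e.g. pathway communities) end up close in cosine space.
#'
#' @param walks List of character vectors from [generate_walks()].
#' @param dim Embedding width; the per-sample network representation defaults
#'   to 500 dimensions elsewhere in the package.
#' @param window,epochs,min_count,negative,alpha,seed Passed to
#'   [train_gene_embeddings()].
#' @return An `embedding_table`.
#' @export
train_node_embeddings <- function(walks, dim = 500, window = 10, epochs = 5,
                                  min_count = 1, negative = 5,
                                  alpha = 0.025, seed = 1L) {
  if (length(walks) == 0) {
    abort("Empty walk set.", class = "tumorsig_config_error")
  }
  train_gene_embeddings(walks, dim = dim, window = window, epochs = epochs,
                        min_count = min_count, negative = negative,
                        alpha = alpha, seed = seed)
}

#' Per-sample network features: mean of member-node embedding vectors
#'
#' Genes absent from the graph (hence from the embedding vocabulary) are
#' skipped; a sample with no embedded genes gets a zero row with a warning.
#'
#' @param cohort A `cohort`.
#' @param table An `embedding_table` from [train_node_embeddings()].
#' @return A `feature_tbl` with columns `net_000` ... tagged `"network"`.
#' @export
embed_samples_network <- function(cohort, table) {
  aggregate_embeddings(cohort, table, "net", "network")
}
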