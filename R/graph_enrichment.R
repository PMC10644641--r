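# Sample-level KNN graphs and the parameter-free linear graph convolution
# that produces the enriched training views X2 (Euclidean graph) and X3
# (cosine graph) from the raw training matrix X1. One propagation layer, no
# learned weights, identity activation: X_aux = D^(-1/2) (A + I) D^(-1/2) X1.

#' Build a symmetrized K-nearest-neighbour sample graph
#'
#' Each sample selects its `k` nearest other samples under the chosen metric
#' (Euclidean distance, or cosine distance `1 - similarity`); the directed
#' relation is then symmetrized by union, giving an undirected graph whose
#' rows have between `k` and `n - 1` neighbours. Distance ties are broken by
#' lower sample index so the graph is deterministic.
#'
#' @param x numeric matrix, samples in rows.
#' @param k number of neighbours, `1 <= k <= n - 1`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return a `neighbor_graph` with fields `adjacency` (binary symmetric, zero
#'   diagonal), `metric`, `k`.
#' @export
build_knn_graph <- function(x, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n - 1)
    stop2("mdwgan_parameter_error", "k = %d out of range [1, %d]", k, n - 1)
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(x))
  } else {
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0))
      stop2("mdwgan_domain_error",
            "cosine distance undefined for all-zero sample row %d",
            which(norms == 0)[1])
    sim <- tcrossprod(x / norms)
    d <- 1 - sim
  }
  # distances are compared at 12 significant digits so that ties arising
  # from discretized coordinates are exact ties regardless of summation
  # order, and the index tie-break below stays deterministic
  d <- signif(d, 12)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # order() is stable on ties, so lower index wins
    nb <- order(di)[seq_len(k)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))  # union symmetrization
  structure(list(adjacency = adj, metric = metric, k = as.integer(k)),
            class = "neighbor_graph")
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Returns `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I`; the self-loop guarantees strictly positive degrees.
#'
#' @param graph a `neighbor_graph` (or a bare binary adjacency matrix).
#' @return symmetric non-negative matrix.
#' @export
normalized_adjacency <- function(graph) {
  a <- if (inherits(graph, "neighbor_graph")) graph$adjacency else as.matrix(graph)
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  at * tcrossprod(dinv)
}

#' One step of linear graph convolution
#'
#' Multiplies the feature matrix by the symmetric-normalized adjacency,
#' smoothing each sample toward its graph neighbours. The activation is the
#' identity and there are no learned weights.
#'
#' @param x numeric matrix with one row per graph node.
#' @param graph a `neighbor_graph` over the same samples.
#' @return matrix of the same shape as `x`.
#' @export
propagate <- function(x, graph) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(graph$adjacency))
    stop2("mdwgan_alignment_error",
          "feature matrix has %d rows but the graph has %d nodes",
          nrow(x), nrow(graph$adjacency))
  normalized_adjacency(graph) %*% x
}

#' Enrich a training set into three critic views
#'
#' Builds the Euclidean and cosine KNN graphs on the training matrix and
#' returns the triple of views fed to the three critics: `x1` the raw matrix,
#' `x2` its Euclidean-graph smoothing, `x3` its cosine-graph smoothing,
#' sharing row order and labels.
#'
#' @param train a normalized [expression_dataset()].
#' @param k neighbours per sample; the training set needs at least `k + 1`
#'   samples.
#' @return an `enriched_views` object with fields `x1`, `x2`, `x3`, `tissue`,
#'   `condition`, `gene_names`.
#' @export
enrich_views <- function(train, k = 5) {
  n <- n_samples(train)
  if (n < k + 1)
    stop2("mdwgan_parameter_error",
          "need at least k + 1 = %d samples, got %d", k + 1, n)
  x1 <- train$values
  g_e <- build_knn_graph(x1, k, "euclidean")
  g_c <- build_knn_graph(x1, k, "cosine")
  structure(list(x1 = x1,
                 x2 = propagate(x1, g_e),
                 x3 = propagate(x1, g_c),
                 tissue = train$tissue,
                 condition = train$condition,
                 gene_names = train$gene_names,
                 k = as.integer(k)),
            class = "enriched_views")
}

#' Export a graph as an edge list
#'
#' Writes one `i<TAB>j` line per undirected edge (i < j, 1-based indices) for
#' inspection.
#'
#' @param graph a `neighbor_graph`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency > 0, arr.ind = TRUE)
  utils::write.table(idx[order(idx[, 1], idx[, 2]), , drop = FALSE], path,
                     sep = "\t", row.names = FALSE, col.names = c("i", "j"),
                     quote = FALSE)
  invisible(path)
}
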