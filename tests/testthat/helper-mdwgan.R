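# Shared fixtures and small independent oracles used across test files.

# A small two-class cohort for pipeline tests.
small_cohort <- function(seed = 1L, n_per_class = 50, n_genes = 10) {
  b <- max(1L, n_genes %/% 3L)
  make_synthetic_cohort(cohort_spec(
    n_genes = n_genes,
    classes = data.frame(tissue = "Lung",
                         condition = c("normal", "cancer"),
                         n_samples = n_per_class),
    block_sizes = c(b, b),
    within_block_correlation = 0.7,
    de_gene_fraction = 0.5,
    effect_size = 3,
    seed = seed))
}

# Wrap a bare matrix as an expression_dataset with the given labels.
as_dataset <- function(x, tissue, condition, gene_names = NULL) {
  gene_names <- gene_names %||% sprintf("gene%03d", seq_len(ncol(x)))
  expression_dataset(x, sprintf("s%04d", seq_len(nrow(x))), gene_names,
                     tissue, condition)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force KNN adjacency: directed k-nearest under the metric with
# lower-index tie-breaking, then union-symmetrized.
brute_knn_adjacency <- function(x, k, metric) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- if (metric == "euclidean") sqrt(sum((x[i, ] - x[j, ])^2))
    else 1 - sum(x[i, ] * x[j, ]) /
      (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
  }
  d <- signif(d, 12)  # same tie quantization the implementation documents
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    # sort by (distance, index): stable lower-index preference on ties
    nb <- cand[order(d[i, cand], cand)][seq_len(k)]
    adj[i, nb] <- 1
  }
  pmax(adj, t(adj))
}

# Direct-summation Pearson correlation of two vectors.
brute_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / (sqrt(sum(am^2)) * sqrt(sum(bm^2)))
}

# Independent implementation of the correlation-structure similarity:
# standardize upper triangles with population moments, sum products over
# pairs, divide by the number of pairs.
brute_dist_score <- function(dxv, dzv) {
  n <- nrow(dxv)
  total <- 0; np <- 0
  ux <- c(); uz <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ux <- c(ux, dxv[i, j]); uz <- c(uz, dzv[i, j])
  }
  mx <- mean(ux); sx <- sqrt(mean((ux - mx)^2))
  mz <- mean(uz); sz <- sqrt(mean((uz - mz)^2))
  for (p in seq_along(ux))
    total <- total + ((ux[p] - mx) / sx) * ((uz[p] - mz) / sz)
  total / length(ux)
}

# Overwrite a model's critic so D(x|y) = w . x + const on the region where
# the pass-through units stay active (large positive bias), giving an exact
# known input gradient for penalty checks.
set_linear_critic <- function(model, w) {
  cri <- model$critic
  for (l in seq_along(cri$W)) {
    cri$W[[l]][] <- 0
    cri$b[[l]][] <- 0
  }
  cri$W[[1]][seq_along(w), 1] <- w
  cri$b[[1]][1] <- 1e3
  cri$W[[2]][1, 1] <- 1
  L <- length(cri$W)
  if (L > 3) for (l in 3:(L - 1)) cri$W[[l]][1, 1] <- 1
  cri$W[[L]][1, 1] <- 1
  model$critic <- cri
  model
}

# Zero out every critic parameter: D identically 0.
set_zero_critic <- function(model) {
  for (l in seq_along(model$critic$W)) {
    model$critic$W[[l]][] <- 0
    model$critic$b[[l]][] <- 0
  }
  model
}
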