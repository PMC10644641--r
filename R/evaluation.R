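# Evaluation suite: gene-gene Pearson matrices, the correlation-structure
# similarity dist(D^X, D^Z), confusion-matrix metrics, and
# train-on-synthetic/test-on-real (TSTR) classification.

#' Gene-gene Pearson correlation matrix
#'
#' Computes the symmetric matrix of pairwise Pearson correlations between
#' gene columns, with unit diagonal.
#'
#' @param x numeric matrix, samples in rows, genes in columns (or an
#'   [expression_dataset()]).
#' @param gene_names gene names for the columns (taken from the dataset when
#'   `x` is one).
#' @param strict error on zero-variance genes (default) instead of returning
#'   `NA` entries.
#' @return a `gene_distance_matrix` with fields `values`, `gene_names`.
#' @export
gene_pearson_matrix <- function(x, gene_names = NULL, strict = TRUE) {
  if (inherits(x, "expression_dataset")) {
    gene_names <- x$gene_names
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(gene_names)) gene_names <- colnames(x)
  if (nrow(x) < 2)
    stop2("mdwgan_parameter_error", "need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (strict && any(sds == 0))
    stop2("mdwgan_degeneracy_error",
          "zero-variance gene: %s", gene_names[which(sds == 0)[1]])
  d <- suppressWarnings(stats::cor(x))
  diag(d) <- 1
  structure(list(values = d, gene_names = as.character(gene_names)),
            class = "gene_distance_matrix")
}

#' Correlation-structure similarity between real and synthetic data
#'
#' Standardizes the upper-triangle entries of each gene correlation matrix by
#' their mean and population standard deviation, sums the products over all
#' gene pairs, and divides by the number of pairs `n(n-1)/2`. The result is
#' the (population-form) Pearson correlation of the two upper triangles:
#' 1 for identical correlation structure, 0 for unrelated, -1 for opposed.
#'
#' @param dx,dz `gene_distance_matrix` objects on the same genes (real and
#'   synthetic, conventionally).
#' @return scalar in `[-1, 1]`.
#' @export
dist_score <- function(dx, dz) {
  if (!identical(dx$gene_names, dz$gene_names))
    stop2("mdwgan_alignment_error", "gene sets of the two matrices differ")
  n <- length(dx$gene_names)
  if (n < 3)
    stop2("mdwgan_parameter_error", "need at least 3 genes")
  ux <- dx$values[upper.tri(dx$values)]
  uz <- dz$values[upper.tri(dz$values)]
  sx <- sqrt(mean((ux - mean(ux))^2))
  sz <- sqrt(mean((uz - mean(uz))^2))
  if (sx == 0 || sz == 0)
    stop2("mdwgan_degeneracy_error",
          "all pairwise correlations equal; similarity undefined")
  sum(((ux - mean(ux)) / sx) * ((uz - mean(uz)) / sz)) / length(ux)
}

#' Confusion-matrix classification metrics
#'
#' Computes accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient from true/false positive/negative counts. Metrics whose
#' denominator is zero are reported as `NA` rather than 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return named list with `accuracy`, `precision`, `recall`, `f1`, `mcc`.
#' @export
#' @examples
#' confusion_metrics(tp = 40, tn = 30, fp = 10, fn = 20)
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  total <- tp + tn + fp + fn
  accuracy <- (tp + tn) / total
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, mcc = mcc)
}

# Internal 2x128 ReLU MLP classifier (cross-entropy, RMSProp), mirroring the
# evaluation protocol's MLP; nnet only offers a single hidden layer.
mlp_classifier_fit <- function(x, y01, seed, hidden = c(128, 128),
                               epochs = 200, batch = 32, lr = 1e-3) {
  net <- mlp_init(c(ncol(x), hidden, 1L), derive_seed(seed, 101L))
  st <- rmsprop_state(net)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 102L, ep), sample.int(n))
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      cache <- mlp_forward(net, x[idx, , drop = FALSE])
      p <- 1 / (1 + exp(-cache$out))
      d_out <- (p - y01[idx]) / length(idx)  # d(mean CE)/d(logit)
      g <- mlp_backward(net, cache, d_out)
      upd <- rmsprop_update(net, g, st, lr)
      net <- upd$net; st <- upd$state
    }
  }
  net
}

mlp_classifier_predict <- function(net, x) {
  as.numeric(mlp_forward(net, x)$out > 0)
}

#' Train-on-synthetic, test-on-real classification
#'
#' Fits a binary normal-vs-cancer classifier on the `generated` dataset and
#' evaluates it on `real_test`, repeating with distinct seeds and averaging
#' the confusion-matrix metrics. Classifiers follow the fixed protocol:
#' random forest with 200 trees, 5-nearest-neighbours, or a 2 x 128-unit
#' ReLU multilayer perceptron. The positive class is `"cancer"`.
#'
#' @param generated training [expression_dataset()] (typically GAN output
#'   with its conditional labels).
#' @param real_test held-out real [expression_dataset()] on the same genes.
#' @param classifier one of `"rf"`, `"knn"`, `"mlp"`.
#' @param repeats number of seeded runs averaged (default 10).
#' @param seed base seed.
#' @return list with mean `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   the per-run metric data frame `runs`, and the pooled last-run
#'   `confusion` counts.
#' @export
tstr_classification_eval <- function(generated, real_test,
                                     classifier = c("rf", "knn", "mlp"),
                                     repeats = 10, seed = 1L) {
  classifier <- match.arg(classifier)
  if (!identical(generated$gene_names, real_test$gene_names))
    stop2("mdwgan_alignment_error", "gene sets differ")
  if (length(unique(generated$condition)) < 2)
    stop2("mdwgan_degeneracy_error",
          "generated set has a single condition class")
  xtr <- generated$values
  ytr <- factor(generated$condition, levels = c("normal", "cancer"))
  xte <- real_test$values
  yte <- factor(real_test$condition, levels = c("normal", "cancer"))
  runs <- vector("list", repeats)
  conf <- NULL
  for (r in seq_len(repeats)) {
    rs <- derive_seed(seed, 200L, r)
    pred <- switch(classifier,
      rf = with_seed(rs, {
        fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
        stats::predict(fit, xte)
      }),
      knn = with_seed(rs, class::knn(xtr, xte, ytr, k = 5)),
      mlp = {
        net <- mlp_classifier_fit(xtr, as.numeric(ytr == "cancer"), rs)
        factor(ifelse(mlp_classifier_predict(net, xte) == 1,
                      "cancer", "normal"),
               levels = c("normal", "cancer"))
      })
    tp <- sum(pred == "cancer" & yte == "cancer")
    tn <- sum(pred == "normal" & yte == "normal")
    fp <- sum(pred == "cancer" & yte == "normal")
    fn <- sum(pred == "normal" & yte == "cancer")
    conf <- list(tp = tp, tn = tn, fp = fp, fn = fn)
    runs[[r]] <- as.data.frame(confusion_metrics(tp, tn, fp, fn))
  }
  runs <- do.call(rbind, runs)
  out <- as.list(colMeans(runs))
  out$runs <- runs
  out$confusion <- conf
  out$classifier <- classifier
  out
}

#' Compare gene-gene correlations on a named gene panel
#'
#' Restricts both datasets to `genes` (e.g. a panel of frequently mutated
#' cancer genes) and returns the pair of Pearson submatrices plus their
#' largest absolute entry-wise difference.
#'
#' @param real,generated [expression_dataset()] objects containing all
#'   `genes`.
#' @param genes character vector of gene names.
#' @return list with `real`, `generated` (`gene_distance_matrix` pair) and
#'   `max_abs_diff`.
#' @export
key_gene_correlation <- function(real, generated, genes) {
  for (ds_name in c("real", "generated")) {
    ds <- if (ds_name == "real") real else generated
    miss <- setdiff(genes, ds$gene_names)
    if (length(miss))
      stop2("mdwgan_lookup_error", "gene %s missing from the %s dataset",
            miss[1], ds_name)
  }
  sub <- function(ds) {
    pos <- match(genes, ds$gene_names)
    gene_pearson_matrix(ds$values[, pos, drop = FALSE], genes)
  }
  dr <- sub(real); dg <- sub(generated)
  list(real = dr, generated = dg,
       max_abs_diff = max(abs(dr$values - dg$values)))
}

#' Full evaluation report
#'
#' Computes the correlation-structure similarity between a real and a
#' generated dataset and, for each requested classifier, the TSTR metrics,
#' optionally adding a key-gene correlation comparison.
#'
#' @param real real [expression_dataset()] (the held-out test split).
#' @param generated generated [expression_dataset()].
#' @param classifiers character subset of `c("rf", "knn", "mlp")`.
#' @param key_genes optional gene panel for [key_gene_correlation()].
#' @param repeats TSTR repeats per classifier.
#' @param seed base seed.
#' @return an `eval_report` list: `dist`, `classifiers` (named metric lists),
#'   `key_genes`.
#' @export
evaluate_generated <- function(real, generated,
                               classifiers = c("rf", "knn", "mlp"),
                               key_genes = NULL, repeats = 10, seed = 1L) {
  dx <- gene_pearson_matrix(real)
  dz <- gene_pearson_matrix(generated)
  res <- list(dist = dist_score(dx, dz), classifiers = list(),
              key_genes = NULL)
  for (cl in classifiers)
    res$classifiers[[cl]] <- tstr_classification_eval(
      generated, real, classifier = cl, repeats = repeats, seed = seed)
  if (!is.null(key_genes))
    res$key_genes <- key_gene_correlation(real, generated, key_genes)
  structure(res, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("dist(D^X, D^Z) = %.4f\n", x$dist))
  for (cl in names(x$classifiers)) {
    m <- x$classifiers[[cl]]
    cat(sprintf(
      "  %-4s accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  mcc %.4f\n",
      cl, m$accuracy, m$precision, m$recall, m$f1, m$mcc))
  }
  if (!is.null(x$key_genes))
    cat(sprintf("  key-gene max |delta r| = %.4f\n", x$key_genes$max_abs_diff))
  invisible(x)
}
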