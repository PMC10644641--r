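# Expression matrix I/O, normalization, gene filtering and stratified splits.
#
# The on-disk convention is a delimited text matrix (samples x genes) whose
# header row holds gene names and whose first column holds sample identifiers,
# plus a separate label table mapping each sample id to a tissue and a
# condition (normal | cancer). Delimiter is sniffed from the file extension:
# ".csv" is comma, anything else tab.

#' Construct an expression dataset
#'
#' Bundles a samples x genes numeric matrix with aligned sample identifiers,
#' gene names, and per-sample tissue/condition labels, validating the
#' structural invariants (unique ids and gene names, finite values, aligned
#' lengths).
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param gene_names character vector of unique gene names.
#' @param tissue character vector of tissue labels, one per sample.
#' @param condition character vector of condition labels (e.g. "normal",
#'   "cancer"), one per sample.
#' @return an object of class `expression_dataset` with fields `values`,
#'   `sample_ids`, `gene_names`, `tissue`, `condition`.
#' @export
#' @examples
#' ds <- expression_dataset(matrix(1:6, 3, 2), c("s1", "s2", "s3"),
#'                          c("gA", "gB"), rep("Lung", 3),
#'                          c("normal", "cancer", "cancer"))
#' dim(ds$values)
expression_dataset <- function(values, sample_ids, gene_names, tissue, condition) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_finite_matrix(values, "expression values")
  n <- nrow(values); m <- ncol(values)
  sample_ids <- as.character(sample_ids)
  gene_names <- as.character(gene_names)
  tissue <- as.character(tissue)
  condition <- as.character(condition)
  if (length(sample_ids) != n || length(tissue) != n || length(condition) != n)
    stop2("mdwgan_format_error",
          "sample ids/labels (%d/%d/%d) do not match the %d matrix rows",
          length(sample_ids), length(tissue), length(condition), n)
  if (length(gene_names) != m)
    stop2("mdwgan_format_error", "%d gene names for %d matrix columns",
          length(gene_names), m)
  if (anyDuplicated(sample_ids))
    stop2("mdwgan_format_error", "duplicate sample id: %s",
          sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(gene_names))
    stop2("mdwgan_format_error", "duplicate gene name: %s",
          gene_names[duplicated(gene_names)][1])
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_names = gene_names, tissue = tissue,
                 condition = condition),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$tissue, x$condition)
  cat(sprintf("  %d tissue(s), conditions: %s\n",
              nrow(tab), paste(colnames(tab), collapse = ", ")))
  invisible(x)
}

#' Number of samples / genes in a dataset
#' @param dataset an `expression_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_genes <- function(dataset) ncol(dataset$values)

sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and its sample labels
#'
#' Reads a delimited expression table (header row = gene names, first column =
#' sample ids) together with a label table (columns `sample_id`, `tissue`,
#' `condition`) and returns a validated [expression_dataset()]. Sample order
#' follows the matrix file; every sample must be present in the label file.
#'
#' @param path path to the expression matrix file (.csv comma, otherwise tab).
#' @param label_path path to the label table.
#' @return an `expression_dataset`.
#' @export
read_expression_table <- function(path, label_path) {
  for (p in c(path, label_path))
    if (!file.exists(p)) stop2("mdwgan_io_error", "file not found: %s", p)
  sep <- sniff_delim(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2)
    stop2("mdwgan_format_error", "expression table %s has no gene columns", path)
  sample_ids <- raw[[1]]
  gene_names <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(gene_names))
  if (any(is.na(vals))) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop2("mdwgan_parse_error",
          "non-numeric value at row %d (sample %s), column %d (gene %s) of %s",
          idx[1], sample_ids[idx[1]], idx[2], gene_names[idx[2]], path)
  }
  lab <- utils::read.table(label_path, sep = sniff_delim(label_path),
                           header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  need <- c("sample_id", "tissue", "condition")
  if (!all(need %in% colnames(lab)))
    stop2("mdwgan_format_error", "label table %s must have columns %s",
          label_path, paste(need, collapse = ", "))
  pos <- match(sample_ids, lab$sample_id)
  if (anyNA(pos))
    stop2("mdwgan_labeling_error", "no label for sample(s): %s",
          paste(utils::head(sample_ids[is.na(pos)], 5), collapse = ", "))
  expression_dataset(vals, sample_ids, gene_names,
                     lab$tissue[pos], lab$condition[pos])
}

#' Write an expression dataset to disk
#'
#' Writes the matrix and label files in the format [read_expression_table()]
#' reads. Values are written with 6 significant digits.
#'
#' @param dataset an `expression_dataset`.
#' @param path output path for the matrix file.
#' @param label_path output path for the label table.
#' @return invisibly, the dataset.
#' @export
write_expression_table <- function(dataset, path, label_path) {
  sep <- sniff_delim(path)
  vals <- signif(dataset$values, 6)
  df <- data.frame(sample_id = dataset$sample_ids,
                   as.data.frame(vals, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  lab <- data.frame(sample_id = dataset$sample_ids, tissue = dataset$tissue,
                    condition = dataset$condition)
  utils::write.table(lab, label_path, sep = sniff_delim(label_path),
                     row.names = FALSE, quote = FALSE)
  invisible(dataset)
}

#' Log/z-score normalize an expression dataset
#'
#' Applies `log2(x + pseudocount)` followed by per-gene z-scoring with the
#' population (divide-by-n) standard deviation. Genes with zero variance after
#' the log transform are dropped with a warning, since correlation-based
#' evaluation is undefined for them.
#'
#' @param dataset an `expression_dataset` of non-negative raw values.
#' @param pseudocount value added before the log; default 1.
#' @return a list with `dataset` (normalized) and `stats`, a
#'   `normalization_stats` object holding `per_gene_mean`, `per_gene_std`,
#'   `log_base` (2) and `pseudocount`, usable with [denormalize()] and
#'   [apply_normalization()].
#' @export
normalize <- function(dataset, pseudocount = 1) {
  x <- dataset$values
  if (any(x < 0))
    stop2("mdwgan_domain_error", "normalize() requires non-negative raw values")
  lg <- log2(x + pseudocount)
  mu <- colMeans(lg)
  sdp <- sqrt(colMeans(sweep(lg, 2, mu)^2))  # population form
  keep <- sdp > 0
  if (!any(keep))
    stop2("mdwgan_degenerate_error", "all genes have zero variance")
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance gene(s): %s",
                    sum(!keep),
                    paste(utils::head(dataset$gene_names[!keep], 5),
                          collapse = ", ")))
    lg <- lg[, keep, drop = FALSE]
    mu <- mu[keep]; sdp <- sdp[keep]
  }
  z <- sweep(sweep(lg, 2, mu), 2, sdp, "/")
  stats <- structure(list(per_gene_mean = unname(mu),
                          per_gene_std = unname(sdp),
                          gene_names = dataset$gene_names[keep],
                          log_base = 2L, pseudocount = pseudocount),
                     class = "normalization_stats")
  out <- expression_dataset(z, dataset$sample_ids, dataset$gene_names[keep],
                            dataset$tissue, dataset$condition)
  list(dataset = out, stats = stats)
}

#' Apply previously fitted normalization statistics
#'
#' Transforms a raw dataset with statistics fitted on another split (typically
#' the training set), so validation/test data share the training scale.
#'
#' @param dataset raw `expression_dataset`.
#' @param stats `normalization_stats` from [normalize()].
#' @return normalized `expression_dataset` restricted to the fitted genes.
#' @export
apply_normalization <- function(dataset, stats) {
  pos <- match(stats$gene_names, dataset$gene_names)
  if (anyNA(pos))
    stop2("mdwgan_alignment_error", "dataset lacks fitted gene(s): %s",
          paste(utils::head(stats$gene_names[is.na(pos)], 5), collapse = ", "))
  x <- dataset$values[, pos, drop = FALSE]
  if (any(x < 0))
    stop2("mdwgan_domain_error", "raw values must be non-negative")
  lg <- log2(x + stats$pseudocount)
  z <- sweep(sweep(lg, 2, stats$per_gene_mean), 2, stats$per_gene_std, "/")
  expression_dataset(z, dataset$sample_ids, stats$gene_names,
                     dataset$tissue, dataset$condition)
}

#' Invert log/z-score normalization
#'
#' Maps normalized values back to the raw scale: `2^(x * std + mean) -
#' pseudocount`, clipped at zero. Genes are realigned by name when the orders
#' differ; a set mismatch is an error.
#'
#' @param dataset normalized `expression_dataset`.
#' @param stats `normalization_stats` fitted on the same gene set.
#' @return raw-scale `expression_dataset`.
#' @export
denormalize <- function(dataset, stats) {
  pos <- match(dataset$gene_names, stats$gene_names)
  if (anyNA(pos) || length(stats$gene_names) != length(dataset$gene_names))
    stop2("mdwgan_alignment_error",
          "gene sets of dataset and normalization stats differ")
  mu <- stats$per_gene_mean[pos]
  sdp <- stats$per_gene_std[pos]
  raw <- 2^(sweep(sweep(dataset$values, 2, sdp, "*"), 2, mu, "+")) -
    stats$pseudocount
  raw[raw < 0] <- 0
  expression_dataset(raw, dataset$sample_ids, dataset$gene_names,
                     dataset$tissue, dataset$condition)
}

#' Restrict a dataset to a keep-list of genes
#'
#' Keeps the intersection of `keep` with the dataset's genes, preserving the
#' original column order. Typically used to apply an externally derived gene
#' list (e.g. genes supported by a protein interaction network).
#'
#' @param dataset an `expression_dataset`.
#' @param keep character vector of gene names to retain.
#' @return filtered `expression_dataset`.
#' @export
filter_genes <- function(dataset, keep) {
  if (length(keep) == 0)
    stop2("mdwgan_parameter_error", "keep list is empty")
  sel <- dataset$gene_names %in% keep
  if (!any(sel))
    stop2("mdwgan_degenerate_error",
          "no gene in the keep list is present in the dataset")
  expression_dataset(dataset$values[, sel, drop = FALSE], dataset$sample_ids,
                     dataset$gene_names[sel], dataset$tissue,
                     dataset$condition)
}

subset_samples <- function(dataset, idx) {
  expression_dataset(dataset$values[idx, , drop = FALSE],
                     dataset$sample_ids[idx], dataset$gene_names,
                     dataset$tissue[idx], dataset$condition[idx])
}

#' Stratified train/test split
#'
#' Randomly splits samples within each (tissue, condition) stratum at
#' `train_fraction` (rounded to nearest, at least one sample per side), so
#' both outputs preserve the stratum proportions. Deterministic given `seed`.
#'
#' @param dataset an `expression_dataset`.
#' @param train_fraction fraction in (0, 1) assigned to the first output.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
stratified_split <- function(dataset, train_fraction, seed) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop2("mdwgan_parameter_error", "train_fraction must lie in (0, 1)")
  strata <- paste(dataset$tissue, dataset$condition, sep = " / ")
  idx_train <- integer(0)
  with_seed(seed, {
    for (s in unique(strata)) {
      members <- which(strata == s)
      ns <- length(members)
      if (ns < 2)
        stop2("mdwgan_stratification_error",
              "stratum '%s' has only %d sample(s); need at least 2", s, ns)
      k <- min(max(1L, round(train_fraction * ns)), ns - 1L)
      idx_train <- c(idx_train, sample(members, k))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n_samples(dataset)), idx_train)
  list(train = subset_samples(dataset, idx_train),
       test = subset_samples(dataset, idx_test))
}

#' Save / load normalization statistics as JSON
#'
#' @param stats a `normalization_stats` object.
#' @param path JSON file path.
#' @return `write_normalization_stats` returns the path invisibly;
#'   `read_normalization_stats` returns the `normalization_stats`.
#' @export
write_normalization_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_stats
#' @export
read_normalization_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_gene_mean = as.numeric(obj$per_gene_mean),
                 per_gene_std = as.numeric(obj$per_gene_std),
                 gene_names = as.character(obj$gene_names),
                 log_base = as.integer(obj$log_base),
                 pseudocount = as.numeric(obj$pseudocount)),
            class = "normalization_stats")
}
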