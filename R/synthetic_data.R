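# Seeded synthetic cohorts with known class structure and block gene-gene
# correlation, so the full pipeline is testable without external downloads.
# Values are drawn directly on the normalized (log/z-score-like) scale: the
# GAN and all correlation metrics operate post-normalization, so that is the
# space worth emulating.

#' Specify a synthetic expression cohort
#'
#' Defines a multi-class Gaussian cohort on the normalized expression scale.
#' Genes are grouped into correlation blocks (equicorrelated within a block at
#' `within_block_correlation`, independent between blocks); a leading fraction
#' of genes is differentially expressed, shifting by `effect_size` standard
#' deviations in the cancer condition.
#'
#' @param n_genes number of genes.
#' @param classes data frame with columns `tissue`, `condition`, `n_samples`
#'   (one row per class).
#' @param block_sizes integer vector of correlation block sizes summing to at
#'   most `n_genes`; remaining genes are independent.
#' @param within_block_correlation correlation inside each block, in `[0, 1)`.
#' @param de_gene_fraction fraction of genes carrying the condition effect.
#' @param effect_size mean shift (in SD units) on differential genes for
#'   condition `"cancer"`.
#' @param noise_sd marginal standard deviation of every gene.
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_genes = 20,
                        classes = data.frame(
                          tissue = c("Lung", "Lung"),
                          condition = c("normal", "cancer"),
                          n_samples = c(100, 100)),
                        block_sizes = c(5, 5),
                        within_block_correlation = 0.8,
                        de_gene_fraction = 0.5,
                        effect_size = 3,
                        noise_sd = 1,
                        seed = 1L) {
  if (n_genes < 1) stop2("mdwgan_parameter_error", "n_genes must be >= 1")
  if (sum(block_sizes) > n_genes)
    stop2("mdwgan_parameter_error", "block sizes exceed the gene count")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop2("mdwgan_parameter_error",
          "within_block_correlation must lie in [0, 1) for a positive definite covariance")
  if (noise_sd <= 0) stop2("mdwgan_parameter_error", "noise_sd must be > 0")
  if (de_gene_fraction < 0 || de_gene_fraction > 1)
    stop2("mdwgan_parameter_error", "de_gene_fraction must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), classes = classes,
                 block_sizes = as.integer(block_sizes),
                 within_block_correlation = within_block_correlation,
                 de_gene_fraction = de_gene_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_sigma <- function(spec) {
  m <- spec$n_genes
  sigma <- diag(m)
  start <- 1L
  for (b in spec$block_sizes) {
    idx <- start:(start + b - 1L)
    sigma[idx, idx] <- spec$within_block_correlation
    diag(sigma)[idx] <- 1
    start <- start + b
  }
  sigma * spec$noise_sd^2
}

#' Draw a synthetic cohort
#'
#' Samples each class from a multivariate normal with the block-correlated
#' covariance implied by the spec; cancer-condition classes shift by
#' `effect_size` SDs on the designated differential genes. Deterministic for a
#' fixed spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return an [expression_dataset()] on the normalized scale.
#' @export
#' @examples
#' ds <- make_synthetic_cohort(cohort_spec(seed = 7))
#' table(ds$tissue, ds$condition)
make_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- cohort_sigma(spec)
  m <- spec$n_genes
  n_de <- round(spec$de_gene_fraction * m)
  shift <- c(rep(spec$effect_size * spec$noise_sd, n_de), rep(0, m - n_de))
  gene_names <- sprintf("gene%03d", seq_len(m))
  blocks <- with_seed(spec$seed, {
    lapply(seq_len(nrow(spec$classes)), function(i) {
      cls <- spec$classes[i, ]
      mu <- if (identical(cls$condition, "cancer")) shift else rep(0, m)
      MASS::mvrnorm(cls$n_samples, mu = mu, Sigma = sigma)
    })
  })
  values <- do.call(rbind, blocks)
  tissue <- rep(spec$classes$tissue, spec$classes$n_samples)
  condition <- rep(spec$classes$condition, spec$classes$n_samples)
  ids <- sprintf("sample%04d", seq_len(nrow(values)))
  expression_dataset(values, ids, gene_names, tissue, condition)
}

#' A tiny fixed dataset for hand-checkable examples
#'
#' Six samples by four genes, two classes, with values chosen so KNN graphs
#' and gene correlation matrices can be verified by hand.
#'
#' @return an [expression_dataset()].
#' @export
make_toy_fixture <- function() {
  values <- matrix(c(
    0.0,  1.0,  0.5, -1.0,
    0.2,  0.8,  0.4, -0.8,
    0.1,  1.2,  0.6, -1.1,
    3.0, -1.0,  2.0,  1.0,
    3.2, -0.8,  2.2,  1.2,
    2.8, -1.2,  1.8,  0.9), nrow = 6, byrow = TRUE)
  expression_dataset(values,
                     sample_ids = paste0("s", 1:6),
                     gene_names = paste0("g", 1:4),
                     tissue = rep("Lung", 6),
                     condition = rep(c("normal", "cancer"), each = 3))
}
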