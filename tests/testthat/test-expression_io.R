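test_that("expression tables round-trip through write and read", {
  ds <- small_cohort(seed = 3, n_per_class = 5, n_genes = 4)
  expr <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ds, expr, lab)
  back <- read_expression_table(expr, lab)
  expect_identical(back$sample_ids, ds$sample_ids)
  expect_identical(back$gene_names, ds$gene_names)
  expect_identical(back$tissue, ds$tissue)
  expect_identical(back$condition, ds$condition)
  # values written with 6 significant digits
  expect_equal(back$values, ds$values, tolerance = 1e-5)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(ds, csv, lab)
  expect_equal(read_expression_table(csv, lab)$values, back$values)
})

test_that("malformed input files raise typed errors", {
  ds <- small_cohort(seed = 3, n_per_class = 3, n_genes = 3)
  expr <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ds, expr, lab)

  # a sample missing from the label file
  labs <- read.delim(lab)
  write.table(labs[-2, ], lab, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_expression_table(expr, lab), class = "mdwgan_labeling_error")
  write.table(labs, lab, sep = "\t", row.names = FALSE, quote = FALSE)

  # duplicated gene column name
  lines <- readLines(expr)
  lines[1] <- sub("gene002", "gene001", lines[1])
  writeLines(lines, expr)
  expect_error(read_expression_table(expr, lab), class = "mdwgan_format_error")

  # non-numeric cell reported with coordinates
  write_expression_table(ds, expr, lab)
  lines <- readLines(expr)
  lines[3] <- sub("^(\\S+\t)\\S+", "\\1oops", lines[3])
  writeLines(lines, expr)
  err <- expect_error(read_expression_table(expr, lab),
                      class = "mdwgan_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "gene001")

  expect_error(read_expression_table("nope.tsv", lab),
               class = "mdwgan_io_error")
})

test_that("normalize matches the hand-worked log2/z-score case", {
  ds <- as_dataset(matrix(c(0, 3, 15), 3, 1), rep("Lung", 3),
                   c("normal", "normal", "cancer"), "gA")
  res <- normalize(ds, pseudocount = 1)
  # log2 gives 0, 2, 4; population sd = sqrt(8/3)
  expect_equal(drop(res$dataset$values), c(-2, 0, 2) / sqrt(8 / 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$stats$per_gene_mean, 2)
  expect_equal(res$stats$per_gene_std, sqrt(8 / 3))
})

test_that("normalized columns have mean 0 and population sd 1", {
  ds <- small_cohort(seed = 5, n_per_class = 20, n_genes = 6)
  raw <- as_dataset(2^ds$values, ds$tissue, ds$condition, ds$gene_names)
  res <- normalize(raw)
  z <- res$dataset$values
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)), 1e-9)
})

test_that("zero-variance genes are dropped with a warning", {
  x <- cbind(c(1, 2, 3), c(7, 7, 7))
  ds <- as_dataset(x, rep("Lung", 3), c("normal", "normal", "cancer"),
                   c("gA", "gConst"))
  expect_warning(res <- normalize(ds), "gConst")
  expect_identical(res$dataset$gene_names, "gA")
  expect_error(
    suppressWarnings(normalize(as_dataset(matrix(7, 3, 1), rep("Lung", 3),
                                          rep("normal", 3), "g"))),
    class = "mdwgan_degenerate_error")
  expect_error(normalize(as_dataset(matrix(-1, 3, 1), rep("Lung", 3),
                                    rep("normal", 3), "g")),
               class = "mdwgan_domain_error")
})

test_that("denormalize inverts normalize and realigns by gene name", {
  ds <- small_cohort(seed = 6, n_per_class = 10, n_genes = 5)
  raw <- as_dataset(2^ds$values, ds$tissue, ds$condition, ds$gene_names)
  res <- normalize(raw)
  back <- denormalize(res$dataset, res$stats)
  expect_equal(back$values, raw$values, tolerance = 1e-6)

  # all-zero normalized matrix returns each gene's geometric-scale mean
  zero <- as_dataset(matrix(0, 4, 5), rep("Lung", 4),
                     rep("normal", 4), res$stats$gene_names)
  geo <- denormalize(zero, res$stats)
  expect_equal(geo$values[1, ],
               setNames(2^res$stats$per_gene_mean - res$stats$pseudocount,
                        res$stats$gene_names))

  # permuted gene order realigns by name
  perm <- sample(ncol(res$dataset$values))
  shuffled <- as_dataset(res$dataset$values[, perm], ds$tissue, ds$condition,
                         res$stats$gene_names[perm])
  back2 <- denormalize(shuffled, res$stats)
  expect_equal(back2$values[, order(perm)], back$values, tolerance = 1e-6,
               ignore_attr = TRUE)

  # disjoint gene sets are an error
  bad <- as_dataset(matrix(0, 2, 2), rep("Lung", 2), rep("normal", 2),
                    c("nope1", "nope2"))
  expect_error(denormalize(bad, res$stats), class = "mdwgan_alignment_error")
})

test_that("apply_normalization reuses training-split statistics", {
  ds <- small_cohort(seed = 8, n_per_class = 15, n_genes = 5)
  raw <- as_dataset(2^ds$values, ds$tissue, ds$condition, ds$gene_names)
  sp <- stratified_split(raw, 0.5, seed = 2)
  res <- normalize(sp$train)
  val <- apply_normalization(sp$test, res$stats)
  expect_identical(val$gene_names, res$stats$gene_names)
  # same transform as normalizing by hand with the training stats
  manual <- sweep(sweep(log2(sp$test$values + 1), 2,
                        res$stats$per_gene_mean),
                  2, res$stats$per_gene_std, "/")
  expect_equal(val$values, manual, ignore_attr = TRUE)
})

test_that("filter_genes keeps order, handles identity and disjoint sets", {
  ds <- small_cohort(seed = 7, n_per_class = 4, n_genes = 5)
  keep <- ds$gene_names[c(4, 2)]  # out of order on purpose
  flt <- filter_genes(ds, keep)
  expect_identical(flt$gene_names, ds$gene_names[c(2, 4)])
  expect_identical(flt$values, ds$values[, c(2, 4)])
  expect_identical(filter_genes(ds, ds$gene_names)$values, ds$values)
  expect_error(filter_genes(ds, c("x", "y")),
               class = "mdwgan_degenerate_error")
  expect_error(filter_genes(ds, character(0)),
               class = "mdwgan_parameter_error")
})

test_that("stratified_split is deterministic and proportion-preserving", {
  ds <- make_synthetic_cohort(cohort_spec(
    n_genes = 4,
    classes = data.frame(tissue = c("Lung", "Lung", "Kidney"),
                         condition = c("normal", "cancer", "cancer"),
                         n_samples = c(40, 60, 20)),
    block_sizes = 2, seed = 4))
  sp1 <- stratified_split(ds, 0.1, seed = 9)
  sp2 <- stratified_split(ds, 0.1, seed = 9)
  expect_identical(sp1$train$sample_ids, sp2$train$sample_ids)
  sp3 <- stratified_split(ds, 0.1, seed = 10)
  expect_false(identical(sp1$train$sample_ids, sp3$train$sample_ids))

  expect_equal(n_samples(sp1$train), 4 + 6 + 2)
  expect_length(intersect(sp1$train$sample_ids, sp1$test$sample_ids), 0)
  expect_setequal(c(sp1$train$sample_ids, sp1$test$sample_ids), ds$sample_ids)
  # per-stratum counts at the rounded fraction
  expect_equal(sum(sp1$train$tissue == "Kidney"), 2)

  # 2-sample stratum at fraction 0.5 gives 1 + 1
  tiny <- as_dataset(matrix(rnorm(8), 2, 4), rep("Lung", 2),
                     rep("normal", 2))
  sp <- stratified_split(tiny, 0.5, seed = 1)
  expect_equal(n_samples(sp$train), 1)
  expect_equal(n_samples(sp$test), 1)

  # singleton stratum is an error naming the stratum
  one <- as_dataset(matrix(rnorm(8), 2, 4), c("Lung", "Kidney"),
                    rep("cancer", 2))
  err <- expect_error(stratified_split(one, 0.5, seed = 1),
                      class = "mdwgan_stratification_error")
  expect_match(conditionMessage(err), "cancer")
  expect_match(conditionMessage(err), "only 1 sample")
})

test_that("normalization stats round-trip through their JSON sidecar", {
  ds <- small_cohort(seed = 9, n_per_class = 6, n_genes = 4)
  raw <- as_dataset(2^ds$values, ds$tissue, ds$condition, ds$gene_names)
  res <- normalize(raw)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization_stats(res$stats, path)
  back <- read_normalization_stats(path)
  expect_equal(back$per_gene_mean, res$stats$per_gene_mean)
  expect_equal(back$per_gene_std, res$stats$per_gene_std)
  expect_identical(back$gene_names, res$stats$gene_names)
  expect_identical(back$pseudocount, res$stats$pseudocount)
})
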