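make_small_model <- function(hidden = c(8, 6), n_genes = 4, seed = 3) {
  codec <- label_codec(c("Lung", "Lung"), c("normal", "cancer"))
  cfg <- gan_config(noise_dim = 5, hidden_sizes = hidden, seed = seed)
  list(model = gan_model(n_genes, codec, cfg), config = cfg, codec = codec)
}

test_that("noise sampling is seeded and standard normal", {
  z1 <- sample_noise(4, 2, seed = 11)
  z2 <- sample_noise(4, 2, seed = 11)
  expect_identical(z1, z2)
  expect_false(identical(z1, sample_noise(4, 2, seed = 12)))
  z <- sample_noise(4000, 3, seed = 13)
  expect_lt(abs(mean(z)), 5 / sqrt(length(z)))
  expect_lt(abs(var(as.vector(z)) - 1), 5 / sqrt(length(z)))
})

test_that("label codec encodes joint classes and rejects unknown labels", {
  codec <- label_codec(c("Lung", "Lung", "Kidney"),
                       c("normal", "cancer", "cancer"))
  expect_equal(codec$width, 3)
  y <- encode_labels(codec, c("Lung", "Kidney"), c("cancer", "cancer"))
  expect_equal(rowSums(y), c(1, 1))
  expect_false(identical(y[1, ], y[2, ]))
  expect_error(encode_labels(codec, "Kidney", "normal"),
               class = "mdwgan_codec_error")
})

test_that("generation is deterministic and respects the architecture", {
  ms <- make_small_model()
  z <- sample_noise(6, 5, seed = 2)
  tis <- rep("Lung", 6); cond <- rep(c("normal", "cancer"), 3)
  x1 <- generate_samples(ms$model, z, tis, cond)
  x2 <- generate_samples(ms$model, z, tis, cond)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(6, 4))

  # a zero final layer forces all-zero output regardless of noise
  m0 <- ms$model
  L <- length(m0$generator$W)
  m0$generator$W[[L]][] <- 0
  m0$generator$b[[L]][] <- 0
  expect_equal(generate_samples(m0, z, tis, cond), matrix(0, 6, 4))
})

test_that("a hand-set one-hidden-unit network reproduces the paper-and-pencil forward pass", {
  codec <- label_codec("Lung", "cancer")
  cfg <- gan_config(noise_dim = 2, hidden_sizes = c(1, 1), seed = 1)
  model <- gan_model(3, codec, cfg)
  g <- model$generator
  # input (z1, z2, y): weights chosen by hand
  g$W[[1]][] <- c(1, -2, 0.5); g$b[[1]] <- 0.25
  g$W[[2]][] <- 3; g$b[[2]] <- -1
  g$W[[3]][] <- c(1, -1, 2); g$b[[3]] <- c(0.1, 0.2, 0.3)
  model$generator <- g
  z <- matrix(c(2, 0.5), 1, 2)
  # h1 = relu(2 - 1 + 0.5 + 0.25) = 1.75; h2 = relu(3 * 1.75 - 1) = 4.25
  expect_equal(generate_samples(model, z, "Lung", "cancer"),
               matrix(c(4.25 + 0.1, -4.25 + 0.2, 8.5 + 0.3), 1, 3),
               tolerance = 1e-12)

  # negative pre-activation is clamped by ReLU
  z2 <- matrix(c(-2, 0), 1, 2)
  # h1 = relu(-2 + 0.5 + 0.25) = 0; h2 = relu(-1) = 0 -> only biases remain
  expect_equal(generate_samples(model, z2, "Lung", "cancer"),
               matrix(c(0.1, 0.2, 0.3), 1, 3))
})

test_that("critic scores are per-row, tied across views, and shape-checked", {
  ms <- make_small_model()
  x <- matrix(rnorm(12), 3, 4)
  tis <- rep("Lung", 3); cond <- c("normal", "normal", "cancer")
  s <- critic_value(ms$model, x, tis, cond)
  expect_length(s, 3)
  # identical rows with identical labels score identically
  xx <- x[c(1, 1, 1), ]
  ss <- critic_value(ms$model, xx, rep("Lung", 3), rep("normal", 3))
  expect_equal(ss[1], ss[2])
  expect_equal(ss[1], ss[3])
  # zero critic scores zero
  m0 <- set_zero_critic(ms$model)
  expect_equal(critic_value(m0, x, tis, cond), rep(0, 3))
  expect_error(critic_value(ms$model, x[, 1:3], tis, cond),
               class = "mdwgan_alignment_error")
})

test_that("gradient penalty matches the analytic critics", {
  ms <- make_small_model(hidden = c(6, 4), n_genes = 3)
  x_real <- matrix(rnorm(15), 5, 3)
  x_fake <- matrix(rnorm(15), 5, 3)
  tis <- rep("Lung", 5); cond <- rep("cancer", 5)

  # critic identically zero: gradient norm 0, penalty = lambda * (0 - 1)^2
  m0 <- set_zero_critic(ms$model)
  expect_equal(gradient_penalty(m0, x_real, x_fake, tis, cond,
                                lambda_gp = 10, seed = 4), 10)

  # linear critic with unit gradient norm: penalty 0
  m1 <- set_linear_critic(ms$model, c(1, 0, 0))
  expect_equal(gradient_penalty(m1, x_real, x_fake, tis, cond,
                                lambda_gp = 10, seed = 4), 0,
               tolerance = 1e-12)

  # gradient norm 2: penalty = 10 * (2 - 1)^2
  m2 <- set_linear_critic(ms$model, c(2, 0, 0))
  expect_equal(gradient_penalty(m2, x_real, x_fake, tis, cond,
                                lambda_gp = 10, seed = 4), 10,
               tolerance = 1e-12)

  # seeded interpolation is reproducible; penalty is never negative
  p1 <- gradient_penalty(ms$model, x_real, x_fake, tis, cond, 10, seed = 8)
  p2 <- gradient_penalty(ms$model, x_real, x_fake, tis, cond, 10, seed = 8)
  expect_identical(p1, p2)
  expect_gte(p1, 0)
  expect_error(gradient_penalty(ms$model, x_real, x_fake[1:3, ], tis, cond),
               class = "mdwgan_alignment_error")
})

test_that("per-view objective composes critic difference and penalty", {
  ms <- make_small_model(n_genes = 3)
  x <- matrix(rnorm(12), 4, 3)
  xf <- matrix(rnorm(12), 4, 3)
  tis <- rep("Lung", 4); cond <- rep("normal", 4)

  # identical real and fake batches null the critic term
  obj <- per_view_objective(ms$model, 1, x, x, tis, cond, ms$config, seed = 2)
  expect_equal(obj$critic_term, 0)

  # zero critic: critic term 0, penalty term lambda_gp
  m0 <- set_zero_critic(ms$model)
  obj0 <- per_view_objective(m0, 2, x, xf, tis, cond, ms$config, seed = 2)
  expect_equal(obj0$critic_term, 0)
  expect_equal(obj0$penalty_term, ms$config$lambda_gp)

  # brute-force check of both terms on a generic critic
  obj1 <- per_view_objective(ms$model, 1, x, xf, tis, cond, ms$config,
                             seed = 9)
  expect_equal(obj1$critic_term,
               mean(critic_value(ms$model, x, tis, cond)) -
                 mean(critic_value(ms$model, xf, tis, cond)),
               tolerance = 1e-12)
  expect_equal(obj1$penalty_term,
               gradient_penalty(ms$model, x, xf, tis, cond,
                                ms$config$lambda_gp, seed = 9))

  # disabled auxiliary views are rejected
  cfg <- ms$config; cfg$views_enabled <- "euclidean"
  expect_error(per_view_objective(ms$model, 3, x, xf, tis, cond, cfg),
               class = "mdwgan_configuration_error")
})

test_that("aggregate losses follow the printed view weighting", {
  # generator: g1 + (lambda_g / 2) (g2 + g3)
  expect_equal(generator_loss(c(1, 2, 4), lambda_g = 0.2), 1.6)
  expect_equal(generator_loss(c(1, 2, 4), lambda_g = 0), 1)
  g <- -0.7
  expect_equal(generator_loss(rep(g, 3), 0.2), g * 1.2)

  mk <- function(c_, p_) list(critic_term = c_, penalty_term = p_)
  # critic terms of 1 with no penalty at the default weight
  expect_equal(discriminator_loss(list(mk(1, 0), mk(1, 0), mk(1, 0)), 0.02),
               -1.02)
  # pure penalties
  expect_equal(discriminator_loss(list(mk(0, 10), mk(0, 10), mk(0, 10)),
                                  0.02), 10.2)
  # lambda_d = 0 reduces to view 1
  expect_equal(discriminator_loss(list(mk(2, 1), mk(99, 99), mk(-5, 7)), 0),
               -1)
  # random affine check against a direct evaluation
  set.seed(41)
  for (rep in 1:20) {
    cs <- rnorm(3); ps <- abs(rnorm(3)); ld <- runif(1); lg <- runif(1)
    expect_equal(
      discriminator_loss(list(mk(cs[1], ps[1]), mk(cs[2], ps[2]),
                              mk(cs[3], ps[3])), ld),
      -(cs[1] + ld / 2 * (cs[2] + cs[3])) +
        (ps[1] + ld / 2 * (ps[2] + ps[3])),
      tolerance = 1e-12)
    gs <- rnorm(3)
    expect_equal(generator_loss(gs, lg), gs[1] + lg / 2 * (gs[2] + gs[3]),
                 tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip models, config and stats through JSON", {
  ms <- make_small_model()
  ds <- small_cohort(seed = 2, n_per_class = 6, n_genes = 4)
  raw <- as_dataset(2^ds$values, ds$tissue, ds$condition, ds$gene_names)
  stats <- normalize(raw)$stats
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(ms$model, path, config = ms$config, stats = stats,
                  gene_names = ds$gene_names)
  back <- load_checkpoint(path)
  z <- sample_noise(5, 5, seed = 6)
  tis <- rep("Lung", 5); cond <- rep("cancer", 5)
  expect_equal(generate_samples(back$model, z, tis, cond),
               generate_samples(ms$model, z, tis, cond))
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(critic_value(back$model, x, tis, cond),
               critic_value(ms$model, x, tis, cond))
  expect_equal(back$config$lambda_gp, ms$config$lambda_gp)
  expect_equal(back$config$hidden_sizes, ms$config$hidden_sizes)
  expect_equal(back$stats$per_gene_mean, stats$per_gene_mean)
  expect_identical(back$gene_names, ds$gene_names)
})
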