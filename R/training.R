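# Adversarial training loop: RMSProp, n_critic critic updates per generator
# update, per-epoch validation scoring by gene-correlation similarity, early
# stopping on patience, full seeded determinism.
#
# Every random draw uses a seed derived from (config$seed, purpose, counter),
# so a run is reproducible and a reference implementation can consume the
# identical random stream:
#   derive_seed(seed, 1) / (seed, 2)      generator / critic initialization
#   derive_seed(seed, 3, epoch)           epoch shuffling
#   derive_seed(seed, 4, t)               critic-step t noise batch
#   derive_seed(seed, 5, t, v)            critic-step t, view v interpolation
#   derive_seed(seed, 6, u)               generator-step u label+noise draw
#   derive_seed(seed, 7)                  validation noise (fixed across
#                                         epochs so score changes reflect the
#                                         model, not noise resampling)

# Early-stopping rule shared by the training loop and early_stopping_trace():
# strict improvement resets the counter; `patience` consecutive
# non-improvements stop the run.
es_init <- function(patience) {
  list(best = -Inf, best_epoch = 0L, bad = 0L, patience = as.integer(patience))
}

es_step <- function(state, score, epoch) {
  improved <- score > state$best
  if (improved) {
    state$best <- score; state$best_epoch <- as.integer(epoch)
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
  }
  list(state = state, improved = improved,
       stop = !improved && state$bad >= state$patience)
}

#' Replay the early-stopping rule on a score sequence
#'
#' Applies the training loop's stopping rule (strict improvement of the
#' validation score; stop after `patience` consecutive non-improvements or at
#' `max_epochs`) to a given score sequence, without training anything.
#'
#' @param scores numeric vector of per-epoch validation scores.
#' @param patience non-negative integer.
#' @param max_epochs cap on epochs (defaults to the sequence length).
#' @return list with `epochs_run`, `best_epoch`, `best_score`, `stop_reason`.
#' @export
early_stopping_trace <- function(scores, patience,
                                 max_epochs = length(scores)) {
  st <- es_init(patience)
  stop_reason <- "max_epochs"
  epochs_run <- min(length(scores), max_epochs)
  for (epoch in seq_len(min(length(scores), max_epochs))) {
    res <- es_step(st, scores[epoch], epoch)
    st <- res$state
    if (res$stop) { stop_reason <- "patience"; epochs_run <- epoch; break }
  }
  list(epochs_run = epochs_run, best_epoch = st$best_epoch,
       best_score = st$best, stop_reason = stop_reason)
}

# Active views: view 1 (raw) always; auxiliary views only when enabled AND
# their loss weight is nonzero, so zero-weight configurations are
# computationally identical to disabled ones (same random stream included).
active_views <- function(config, for_generator) {
  w_aux <- if (for_generator) config$lambda_g / 2 else config$lambda_d / 2
  views <- list(list(index = 1L, name = "raw", weight = 1))
  if ("euclidean" %in% config$views_enabled && w_aux > 0)
    views <- c(views, list(list(index = 2L, name = "euclidean", weight = w_aux)))
  if ("cosine" %in% config$views_enabled && w_aux > 0)
    views <- c(views, list(list(index = 3L, name = "cosine", weight = w_aux)))
  views
}

# One critic update on a batch (aligned rows across the three views).
critic_step <- function(model, opt_state, views_x, y, config, step_id) {
  n <- nrow(y)
  z <- sample_noise(n, config$noise_dim, derive_seed(config$seed, 4L, step_id))
  fake <- mlp_forward(model$generator, cbind(z, y))$out
  views <- active_views(config, for_generator = FALSE)
  grads <- grads_zero(model$critic)
  cts <- rep(NA_real_, 3); pts <- rep(NA_real_, 3)
  fake_coef <- 0
  for (v in views) {
    xv <- views_x[[v$index]]
    cache_r <- mlp_forward(model$critic, cbind(xv, y))
    out_r <- cache_r$out
    # maximize mean D(real): gradient of the minimized loss is -w/n per row
    br <- mlp_backward(model$critic, cache_r,
                       matrix(-v$weight / n, n, 1))
    grads <- grads_add(grads, br)
    eps <- with_seed(derive_seed(config$seed, 5L, step_id, v$index),
                     stats::runif(n))
    xhat <- xv * eps + fake * (1 - eps)
    gp <- gp_value_grads(model$critic, xhat, y, config$lambda_gp)
    grads <- grads_add(grads, gp$grads, weight = v$weight)
    fake_coef <- fake_coef + v$weight
    cts[v$index] <- mean(out_r)
    pts[v$index] <- gp$value
  }
  cache_f <- mlp_forward(model$critic, cbind(fake, y))
  out_f <- cache_f$out
  bf <- mlp_backward(model$critic, cache_f,
                     matrix(fake_coef / n, n, 1))
  grads <- grads_add(grads, bf)
  cts <- cts - mean(out_f)
  loss <- -sum(vapply(views, `[[`, numeric(1), "weight") *
                 cts[vapply(views, `[[`, integer(1), "index")]) +
    sum(vapply(views, `[[`, numeric(1), "weight") *
          pts[vapply(views, `[[`, integer(1), "index")])
  if (!is.finite(loss))
    stop2("mdwgan_divergence_error",
          "non-finite critic loss at step %d", step_id)
  upd <- rmsprop_update(model$critic, grads, opt_state,
                        config$learning_rate)
  model$critic <- upd$net
  list(model = model, opt_state = upd$state, loss = loss,
       critic_terms = cts, penalty_terms = pts)
}

# One generator update. With a fully tied critic the per-view generator terms
# coincide, so the aggregate loss is (1 + sum of auxiliary weights) times
# -mean D(G(Z|Y)|Y); the coefficient is assembled from the active views.
generator_step <- function(model, opt_state, labels_pool, config, step_id) {
  n <- config$batch_size
  draw <- with_seed(derive_seed(config$seed, 6L, step_id), {
    idx <- sample.int(nrow(labels_pool), n, replace = TRUE)
    list(idx = idx,
         z = matrix(stats::rnorm(n * config$noise_dim), n, config$noise_dim))
  })
  y <- encode_labels(model$codec, labels_pool$tissue[draw$idx],
                     labels_pool$condition[draw$idx])
  coef <- sum(vapply(active_views(config, for_generator = TRUE),
                     `[[`, numeric(1), "weight"))
  cache_g <- mlp_forward(model$generator, cbind(draw$z, y))
  fake <- cache_g$out
  cache_c <- mlp_forward(model$critic, cbind(fake, y))
  loss <- -coef * mean(cache_c$out)
  if (!is.finite(loss))
    stop2("mdwgan_divergence_error",
          "non-finite generator loss at step %d", step_id)
  bc <- mlp_backward(model$critic, cache_c, matrix(-coef / n, n, 1))
  d_fake <- bc$d_input[, seq_len(model$n_genes), drop = FALSE]
  bg <- mlp_backward(model$generator, cache_g, d_fake)
  upd <- rmsprop_update(model$generator, bg, opt_state, config$learning_rate)
  model$generator <- upd$net
  list(model = model, opt_state = upd$state, loss = loss)
}

validation_score <- function(model, validation, dx_val, config) {
  z <- sample_noise(n_samples(validation), config$noise_dim,
                    derive_seed(config$seed, 7L))
  gen <- generate_samples(model, z, validation$tissue, validation$condition)
  tryCatch({
    dz <- gene_pearson_matrix(gen, validation$gene_names)
    dist_score(dx_val, dz)
  }, error = function(e) -1)  # degenerate generator output scores worst
}

#' Train the multi-discriminator conditional WGAN-GP
#'
#' Alternates `n_critic` critic updates (on minibatches drawn with aligned
#' row indices across the three views) with one generator update, both under
#' RMSProp. After every epoch the model generates a batch matching the
#' validation set's size and labels and scores it by [dist_score()] against
#' the validation gene-correlation matrix; training stops when that score has
#' not strictly improved for `patience` consecutive epochs, or at
#' `max_epochs`. The returned model is the checkpoint from the best epoch.
#'
#' @param views an [enrich_views()] triple built from the training split.
#' @param validation an [expression_dataset()] disjoint from training, on the
#'   same genes and normalized scale.
#' @param config a [gan_config()].
#' @return list with `model` (best-epoch [gan_model()]), `history` (one row
#'   per epoch: losses, per-view terms, validation score), `best_epoch`,
#'   `best_score`, `stop_reason` (`"patience"` or `"max_epochs"`).
#' @export
train_mdwgan <- function(views, validation, config = gan_config()) {
  stopifnot(inherits(views, "enriched_views"))
  if (!identical(views$gene_names, validation$gene_names))
    stop2("mdwgan_alignment_error",
          "training views and validation set have different gene sets")
  n_train <- nrow(views$x1)
  labels_pool <- data.frame(tissue = views$tissue,
                            condition = views$condition)
  codec <- label_codec(c(views$tissue, validation$tissue),
                       c(views$condition, validation$condition))
  model <- gan_model(length(views$gene_names), codec, config)
  opt_c <- rmsprop_state(model$critic)
  opt_g <- rmsprop_state(model$generator)
  y_all <- encode_labels(codec, views$tissue, views$condition)
  dx_val <- gene_pearson_matrix(validation$values, validation$gene_names)

  history <- vector("list", config$max_epochs)
  es <- es_init(config$patience)
  best_model <- model; stop_reason <- "max_epochs"
  critic_steps <- 0L; gen_steps <- 0L; since_gen <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 3L, epoch),
                     sample.int(n_train))
    starts <- seq(1L, n_train, by = config$batch_size)
    d_losses <- c(); g_losses <- c()
    ct_acc <- matrix(NA_real_, 0, 3); pt_acc <- matrix(NA_real_, 0, 3)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n_train)]
      views_x <- list(views$x1[idx, , drop = FALSE],
                      views$x2[idx, , drop = FALSE],
                      views$x3[idx, , drop = FALSE])
      critic_steps <- critic_steps + 1L
      cs <- critic_step(model, opt_c, views_x,
                        y_all[idx, , drop = FALSE], config, critic_steps)
      model <- cs$model; opt_c <- cs$opt_state
      d_losses <- c(d_losses, cs$loss)
      ct_acc <- rbind(ct_acc, cs$critic_terms)
      pt_acc <- rbind(pt_acc, cs$penalty_terms)
      since_gen <- since_gen + 1L
      if (since_gen == config$n_critic) {
        gen_steps <- gen_steps + 1L
        gs <- generator_step(model, opt_g, labels_pool, config, gen_steps)
        model <- gs$model; opt_g <- gs$opt_state
        g_losses <- c(g_losses, gs$loss)
        since_gen <- 0L
      }
    }
    score <- validation_score(model, validation, dx_val, config)
    history[[epoch]] <- data.frame(
      epoch = epoch,
      d_loss = mean(d_losses),
      g_loss = if (length(g_losses)) mean(g_losses) else NA_real_,
      critic_term_1 = mean(ct_acc[, 1]),
      critic_term_2 = mean(ct_acc[, 2]),
      critic_term_3 = mean(ct_acc[, 3]),
      penalty_term_1 = mean(pt_acc[, 1]),
      penalty_term_2 = mean(pt_acc[, 2]),
      penalty_term_3 = mean(pt_acc[, 3]),
      val_score = score)
    res <- es_step(es, score, epoch)
    es <- res$state
    if (res$improved) best_model <- model
    if (res$stop) { stop_reason <- "patience"; break }
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  structure(list(model = best_model, history = history,
                 best_epoch = es$best_epoch, best_score = es$best,
                 stop_reason = stop_reason,
                 critic_steps = critic_steps, gen_steps = gen_steps),
            class = "mdwgan_fit")
}

#' @export
print.mdwgan_fit <- function(x, ...) {
  cat(sprintf(
    "mdwgan fit: %d epoch(s), best validation dist = %.4f at epoch %d (%s)\n",
    nrow(x$history), x$best_score, x$best_epoch, x$stop_reason))
  invisible(x)
}

#' Train an ablation variant
#'
#' `full` uses both auxiliary views, `euclidean_only` / `cosine_only` keep a
#' single auxiliary view (its aggregate-loss coefficient stays `lambda/2`,
#' the absent view's term being zero), and `none` is the single-discriminator
#' conditional WGAN-GP reduction.
#'
#' @param views an [enrich_views()] triple.
#' @param validation validation [expression_dataset()].
#' @param config a [gan_config()]; its `views_enabled` is overridden.
#' @param variant one of `"full"`, `"euclidean_only"`, `"cosine_only"`,
#'   `"none"`.
#' @return as [train_mdwgan()].
#' @export
run_ablation <- function(views, validation, config = gan_config(),
                         variant = c("full", "euclidean_only", "cosine_only",
                                     "none")) {
  variant <- match.arg(variant)
  config$views_enabled <- switch(variant,
                                 full = c("euclidean", "cosine"),
                                 euclidean_only = "euclidean",
                                 cosine_only = "cosine",
                                 none = character(0))
  train_mdwgan(views, validation, config)
}
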