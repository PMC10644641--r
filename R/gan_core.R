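# Conditional generator, weight-sharing critic, gradient penalty, and the
# per-view and aggregate adversarial objectives.
#
# One generator G maps [noise, one-hot label] to a gene expression vector.
# A single critic parameter set D is evaluated on all three data views
# ("weight sharing" read as fully tied critics): for view i the per-view
# objective is
#   V(D_i, G) = E[D(X_i|Y)] - E[D(G(Z|Y)|Y)]
#             + lambda_gp E[(||grad_xhat D(xhat|Y)||_2 - 1)^2]
# and the aggregate losses weight the auxiliary views by lambda_g/2
# (generator) and lambda_d/2 (critic).

#' Training configuration
#'
#' Holds every tunable of the model and training loop. Defaults follow the
#' published setting: two 256-unit ReLU hidden layers, gradient penalty
#' weight 10, auxiliary-view weights `lambda_g = 0.2` / `lambda_d = 0.02`,
#' RMSProp at learning rate 5e-4, at most 500 epochs with patience 20 on the
#' validation correlation-similarity score.
#'
#' @param noise_dim generator noise dimension.
#' @param hidden_sizes hidden layer widths shared by generator and critic.
#' @param lambda_gp gradient penalty weight (lambda).
#' @param lambda_g auxiliary-view weight in the generator objective.
#' @param lambda_d auxiliary-view weight in the critic objective.
#' @param learning_rate RMSProp learning rate.
#' @param n_critic critic updates per generator update.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without strict validation improvement before
#'   stopping.
#' @param knn_k neighbours for the enrichment graphs.
#' @param views_enabled which auxiliary views the critic trains on: a subset
#'   of `c("euclidean", "cosine")`. Empty set plus `lambda_g = lambda_d = 0`
#'   recovers a plain single-discriminator conditional WGAN-GP.
#' @param seed integer seed governing all randomness of a run.
#' @return a `gan_config` object.
#' @export
gan_config <- function(noise_dim = 128,
                       hidden_sizes = c(256, 256),
                       lambda_gp = 10,
                       lambda_g = 0.2,
                       lambda_d = 0.02,
                       learning_rate = 5e-4,
                       n_critic = 5,
                       batch_size = 32,
                       max_epochs = 500,
                       patience = 20,
                       knn_k = 5,
                       views_enabled = c("euclidean", "cosine"),
                       seed = 1L) {
  stopifnot(noise_dim >= 1, all(hidden_sizes >= 1), lambda_gp >= 0,
            lambda_g >= 0, lambda_d >= 0, learning_rate > 0, n_critic >= 1,
            batch_size >= 1, max_epochs >= 1, patience >= 0, knn_k >= 1)
  if (!all(views_enabled %in% c("euclidean", "cosine")))
    stop2("mdwgan_configuration_error",
          "views_enabled must be a subset of euclidean, cosine")
  structure(list(noise_dim = as.integer(noise_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 lambda_gp = lambda_gp, lambda_g = lambda_g,
                 lambda_d = lambda_d, learning_rate = learning_rate,
                 n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 knn_k = as.integer(knn_k),
                 views_enabled = as.character(views_enabled),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# --- conditional label codec -------------------------------------------------

#' Build a label codec for (tissue, condition) pairs
#'
#' The conditional label Y is the one-hot indicator of the joint
#' (tissue, condition) class, concatenated to both the generator and critic
#' inputs.
#'
#' @param tissue,condition character vectors defining the known classes.
#' @return a `label_codec` with the sorted class table.
#' @export
label_codec <- function(tissue, condition) {
  cls <- unique(data.frame(tissue = as.character(tissue),
                           condition = as.character(condition)))
  cls <- cls[order(cls$tissue, cls$condition), , drop = FALSE]
  rownames(cls) <- NULL
  structure(list(classes = cls, width = nrow(cls)), class = "label_codec")
}

#' Encode labels as one-hot indicator rows
#'
#' @param codec a [label_codec()].
#' @param tissue,condition label vectors of equal length.
#' @return binary matrix with one row per sample and one column per class.
#' @export
encode_labels <- function(codec, tissue, condition) {
  key <- paste(codec$classes$tissue, codec$classes$condition, sep = "\r")
  pos <- match(paste(as.character(tissue), as.character(condition), sep = "\r"),
               key)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop2("mdwgan_codec_error", "unknown label (%s, %s)",
          tissue[bad], condition[bad])
  }
  y <- matrix(0, length(pos), codec$width)
  y[cbind(seq_along(pos), pos)] <- 1
  y
}

# --- model -------------------------------------------------------------------

#' Initialize a GAN model
#'
#' Creates the generator (input `noise_dim + label width`, output `n_genes`)
#' and the single shared critic (input `n_genes + label width`, output 1),
#' both with the configured ReLU hidden stack and linear output layers.
#'
#' @param n_genes number of genes generated/criticized.
#' @param codec a [label_codec()] for the conditional labels.
#' @param config a [gan_config()].
#' @return a `gan_model` holding `generator`, `critic`, `codec`, `n_genes`,
#'   `noise_dim`.
#' @export
gan_model <- function(n_genes, codec, config = gan_config()) {
  gen <- mlp_init(c(config$noise_dim + codec$width, config$hidden_sizes,
                    n_genes),
                  derive_seed(config$seed, 1L))
  cri <- mlp_init(c(n_genes + codec$width, config$hidden_sizes, 1L),
                  derive_seed(config$seed, 2L))
  structure(list(generator = gen, critic = cri, codec = codec,
                 n_genes = as.integer(n_genes),
                 noise_dim = config$noise_dim),
            class = "gan_model")
}

#' Draw generator input noise
#'
#' @param n number of rows.
#' @param noise_dim columns.
#' @param seed integer seed; the draw is deterministic given it.
#' @return `n x noise_dim` matrix of standard normal draws.
#' @export
sample_noise <- function(n, noise_dim, seed) {
  stopifnot(n >= 1, noise_dim >= 1)
  with_seed(seed, matrix(stats::rnorm(n * noise_dim), n, noise_dim))
}

#' Generate synthetic expression rows
#'
#' Runs the generator forward on noise concatenated with encoded labels.
#' Outputs are unbounded reals on the normalized expression scale.
#'
#' @param model a [gan_model()].
#' @param z noise matrix (`n x noise_dim`).
#' @param tissue,condition labels, one per noise row.
#' @return `n x n_genes` matrix.
#' @export
generate_samples <- function(model, z, tissue, condition) {
  if (ncol(z) != model$noise_dim)
    stop2("mdwgan_alignment_error", "noise has %d columns, expected %d",
          ncol(z), model$noise_dim)
  y <- encode_labels(model$codec, tissue, condition)
  if (nrow(y) != nrow(z))
    stop2("mdwgan_alignment_error", "%d noise rows but %d labels",
          nrow(z), nrow(y))
  mlp_forward(model$generator, cbind(z, y))$out
}

#' Critic score of expression rows
#'
#' All three views share this mapping (fully tied critic weights).
#'
#' @param model a [gan_model()].
#' @param x expression matrix (`n x n_genes`).
#' @param tissue,condition labels aligned to rows of `x`.
#' @return numeric vector of unbounded scores, one per row.
#' @export
critic_value <- function(model, x, tissue, condition) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_genes)
    stop2("mdwgan_alignment_error", "x has %d columns, expected %d genes",
          ncol(x), model$n_genes)
  y <- encode_labels(model$codec, tissue, condition)
  if (nrow(y) != nrow(x))
    stop2("mdwgan_alignment_error", "%d rows but %d labels", nrow(x), nrow(y))
  drop(mlp_forward(model$critic, cbind(x, y))$out)
}

# Internal: penalty value + critic parameter gradients at given interpolates.
# The gradient is taken with respect to the expression block of the critic
# input only (labels are not interpolated).
gp_value_grads <- function(critic, xhat, y, lambda_gp, want_grads = TRUE) {
  n <- nrow(xhat)
  d <- ncol(xhat)
  cache <- mlp_forward(critic, cbind(xhat, y))
  ig <- mlp_input_grad(critic, cache)
  gx <- ig$grad[, seq_len(d), drop = FALSE]
  norms <- sqrt(rowSums(gx^2))
  value <- lambda_gp * mean((norms - 1)^2)
  if (!want_grads) return(list(value = value))
  # d penalty / d grad_x, guarded at the (measure-zero) non-differentiable 0
  coef <- ifelse(norms > 0, 2 * (norms - 1) / norms, 0)
  q <- gx * coef
  q_full <- cbind(q, matrix(0, n, ncol(y)))
  grads <- mlp_gp_grads(critic, cache, ig, q_full, scale = lambda_gp / n)
  list(value = value, grads = grads)
}

#' WGAN gradient penalty
#'
#' Interpolates `xhat = eps * x_real + (1 - eps) * x_fake` with a per-sample
#' uniform `eps` and returns `lambda_gp * mean((||grad_xhat D(xhat|y)||_2 -
#' 1)^2)`. The gradient is taken with respect to the expression input; the
#' conditional label is held fixed.
#'
#' @param model a [gan_model()].
#' @param x_real,x_fake matrices of identical shape.
#' @param tissue,condition labels aligned to rows.
#' @param lambda_gp penalty weight.
#' @param seed seed for the interpolation draw.
#' @return non-negative scalar.
#' @export
gradient_penalty <- function(model, x_real, x_fake, tissue, condition,
                             lambda_gp = 10, seed = 1L) {
  if (!all(dim(x_real) == dim(x_fake)))
    stop2("mdwgan_alignment_error", "x_real and x_fake shapes differ")
  eps <- with_seed(seed, stats::runif(nrow(x_real)))
  xhat <- x_real * eps + x_fake * (1 - eps)
  y <- encode_labels(model$codec, tissue, condition)
  gp_value_grads(model$critic, xhat, y, lambda_gp, want_grads = FALSE)$value
}

#' Per-view critic objective terms
#'
#' For view `i` returns the Wasserstein critic term `mean D(X_i|Y) - mean
#' D(X'|Y)` and the gradient penalty term with interpolation toward that
#' view's real samples.
#'
#' @param model a [gan_model()].
#' @param view_index 1 (raw), 2 (Euclidean view) or 3 (cosine view); views 2
#'   and 3 must be enabled in `config`.
#' @param x_i real samples of the view.
#' @param x_fake generated samples for the same labels.
#' @param tissue,condition labels aligned to rows.
#' @param config a [gan_config()].
#' @param seed seed for the penalty interpolation.
#' @return list with `critic_term` and `penalty_term`.
#' @export
per_view_objective <- function(model, view_index, x_i, x_fake, tissue,
                               condition, config, seed = config$seed) {
  stopifnot(view_index %in% 1:3)
  view_name <- c("raw", "euclidean", "cosine")[view_index]
  if (view_index > 1 && !(view_name %in% config$views_enabled))
    stop2("mdwgan_configuration_error", "view '%s' is disabled", view_name)
  ct <- mean(critic_value(model, x_i, tissue, condition)) -
    mean(critic_value(model, x_fake, tissue, condition))
  pt <- gradient_penalty(model, x_i, x_fake, tissue, condition,
                         lambda_gp = config$lambda_gp, seed = seed)
  if (!is.finite(ct) || !is.finite(pt))
    stop2("mdwgan_divergence_error", "non-finite objective for view %d",
          view_index)
  list(critic_term = ct, penalty_term = pt)
}

#' Aggregate generator loss
#'
#' Combines the per-view generator terms `g_i = -mean D(G(Z|Y)|Y)` as
#' `g1 + (lambda_g / 2) * (g2 + g3)`. With `lambda_g = 0` this is the
#' single-discriminator reduction.
#'
#' @param view_losses numeric vector `c(g1, g2, g3)`.
#' @param lambda_g auxiliary weight.
#' @return scalar loss.
#' @export
generator_loss <- function(view_losses, lambda_g) {
  stopifnot(length(view_losses) == 3)
  view_losses[1] + lambda_g / 2 * (view_losses[2] + view_losses[3])
}

#' Aggregate critic loss (minimized form)
#'
#' Takes the three `(critic_term, penalty_term)` pairs and returns
#' `-(c1 + lambda_d/2 (c2 + c3)) + (p1 + lambda_d/2 (p2 + p3))`: the critic
#' maximizes the weighted Wasserstein terms while the penalties enter the
#' minimized loss with positive sign.
#'
#' @param view_objectives list of three lists with `critic_term`,
#'   `penalty_term`.
#' @param lambda_d auxiliary weight.
#' @return scalar loss.
#' @export
discriminator_loss <- function(view_objectives, lambda_d) {
  stopifnot(length(view_objectives) == 3)
  cts <- vapply(view_objectives, `[[`, numeric(1), "critic_term")
  pts <- vapply(view_objectives, `[[`, numeric(1), "penalty_term")
  w <- c(1, lambda_d / 2, lambda_d / 2)
  -sum(w * cts) + sum(w * pts)
}

# --- checkpoints -------------------------------------------------------------

# Weights are stored flattened (column-major) with explicit dims so the JSON
# round-trip is unambiguous.
net_to_list <- function(net) {
  list(sizes = net$sizes,
       W = lapply(net$W, function(w) list(dim = dim(w), data = as.numeric(w))),
       b = net$b)
}

net_from_list <- function(obj) {
  W <- lapply(obj$W, function(w)
    matrix(as.numeric(w$data), as.integer(w$dim[1]), as.integer(w$dim[2])))
  list(W = W, b = lapply(obj$b, as.numeric), sizes = as.integer(obj$sizes))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned JSON archives holding the generator and critic
#' parameters, the label codec, the training configuration, and (optionally)
#' the normalization statistics needed to return generated data to the raw
#' scale.
#'
#' @param model a [gan_model()].
#' @param path output JSON path.
#' @param config the [gan_config()] used for training.
#' @param stats optional `normalization_stats`.
#' @param gene_names optional gene name vector stored for bookkeeping.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` a list
#'   with `model`, `config`, `stats`, `gene_names`.
#' @export
save_checkpoint <- function(model, path, config = NULL, stats = NULL,
                            gene_names = NULL) {
  obj <- list(format = "mdwgan-checkpoint", version = 1L,
              generator = net_to_list(model$generator),
              critic = net_to_list(model$critic),
              codec = list(tissue = model$codec$classes$tissue,
                           condition = model$codec$classes$condition),
              n_genes = model$n_genes, noise_dim = model$noise_dim,
              config = if (!is.null(config)) unclass(config),
              stats = if (!is.null(stats)) unclass(stats),
              gene_names = gene_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "mdwgan-checkpoint"))
    stop2("mdwgan_format_error", "%s is not a checkpoint file", path)
  codec <- label_codec(obj$codec$tissue, obj$codec$condition)
  model <- structure(list(generator = net_from_list(obj$generator),
                          critic = net_from_list(obj$critic),
                          codec = codec, n_genes = as.integer(obj$n_genes),
                          noise_dim = as.integer(obj$noise_dim)),
                     class = "gan_model")
  config <- if (!is.null(obj$config)) {
    do.call(gan_config, obj$config[names(obj$config) %in%
                                     names(formals(gan_config))])
  }
  stats <- if (!is.null(obj$stats) && length(obj$stats)) {
    structure(list(per_gene_mean = as.numeric(obj$stats$per_gene_mean),
                   per_gene_std = as.numeric(obj$stats$per_gene_std),
                   gene_names = as.character(obj$stats$gene_names),
                   log_base = as.integer(obj$stats$log_base),
                   pseudocount = as.numeric(obj$stats$pseudocount)),
              class = "normalization_stats")
  }
  list(model = model, config = config, stats = stats,
       gene_names = obj$gene_names)
}
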