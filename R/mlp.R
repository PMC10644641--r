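# Dense feed-forward network primitives on BLAS matrix ops. Layers are stored
# input-major: W[[l]] is (d_{l-1} x d_l), b[[l]] length d_l, so a batch X
# (rows = samples) propagates as relu(X %*% W + b). Hidden layers are ReLU,
# the output layer is linear.
#
# The WGAN-GP penalty needs the gradient of (||grad_x D(x)|| - 1)^2 with
# respect to the critic WEIGHTS, i.e. a double backward pass. For a ReLU MLP
# this has a closed form once the activation masks are frozen (the a.e.
# derivative): with C_l the reverse-pass coefficients of the input gradient
# (C_{L+1} = 1, C_l = M_l (C_{l+1} W_{l+1}^T)) and R_l the forward-mode pass
# of the penalty gradient q through the same masked linear maps
# (R_0 = q, R_l = M_l (R_{l-1} W_l)), the weight gradient of q . grad_x D is
# dW_l = R_{l-1}^T C_l and all bias gradients vanish. mlp_gp_grads below
# implements exactly this.

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      # He initialization for the ReLU hidden stack
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b, sizes = as.integer(sizes))
  })
}

# Forward pass; keeps activations A[[l]] (A[[1]] is the input) and ReLU masks
# M[[l]] for the hidden layers, as needed by the backward passes.
mlp_forward <- function(net, x) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  M <- vector("list", L)
  A[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      M[[l]] <- (z > 0) * 1
      A[[l + 1L]] <- z * M[[l]]
    } else {
      A[[l + 1L]] <- z
    }
  }
  list(out = A[[L + 1L]], A = A, M = M)
}

# Standard backward pass from d(loss)/d(out); returns per-layer weight/bias
# gradients and the gradient with respect to the input batch.
mlp_backward <- function(net, cache, d_out) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * cache$M[[l - 1L]]
    else delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, d_input = delta)
}

# Gradient of the (scalar-output) network with respect to each input row,
# plus the reverse coefficients C[[l]] reused by mlp_gp_grads.
mlp_input_grad <- function(net, cache) {
  L <- length(net$W)
  n <- nrow(cache$out)
  C <- vector("list", L + 1L)
  C[[L + 1L]] <- matrix(1, n, 1)
  delta <- C[[L + 1L]]
  for (l in rev(seq_len(L))) {
    delta <- delta %*% t(net$W[[l]])
    if (l > 1L) delta <- delta * cache$M[[l - 1L]]
    C[[l]] <- delta
  }
  list(grad = C[[1L]], C = C)
}

# Weight gradients of sum_i q_i . grad_{x_i} D (masks frozen); biases get
# zero gradient because the input gradient does not depend on them.
mlp_gp_grads <- function(net, cache, ig, q_full, scale = 1) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  r <- q_full
  for (l in seq_len(L)) {
    gW[[l]] <- crossprod(r, ig$C[[l + 1L]]) * scale
    gb[[l]] <- rep(0, length(net$b[[l]]))
    if (l < L) r <- (r %*% net$W[[l]]) * cache$M[[l]]
  }
  list(W = gW, b = gb)
}

grads_zero <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(v) v * 0))
}

grads_add <- function(g1, g2, weight = 1) {
  list(W = Map(function(a, b) a + weight * b, g1$W, g2$W),
       b = Map(function(a, b) a + weight * b, g1$b, g2$b))
}

# RMSProp with the usual decay-0.9 running mean of squared gradients.
rmsprop_state <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(v) v * 0))
}

rmsprop_update <- function(net, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (l in seq_along(net$W)) {
    state$W[[l]] <- rho * state$W[[l]] + (1 - rho) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * grads$W[[l]] / (sqrt(state$W[[l]]) + eps)
    state$b[[l]] <- rho * state$b[[l]] + (1 - rho) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * grads$b[[l]] / (sqrt(state$b[[l]]) + eps)
  }
  list(net = net, state = state)
}
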