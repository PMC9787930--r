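# Internal neural-network engine for the depthwise-separable classifier.
#
# Batched activations are stored as a (V * B) x C matrix: row (b-1)*V + v is
# spatial voxel v (column-major linear index) of sample b, columns are
# channels. Depthwise convolutions run through compiled gather/scatter
# kernels (src/dwconv.cpp); pointwise convolutions, batch norm and fully
# connected layers are BLAS matrix ops.

# Gather-index map of a stride-2, kernel-3, pad-1 convolution: out_shape is
# ceil(in/2); idx[o, k] is the 1-based input voxel read by kernel tap k at
# output voxel o (0 = zero padding).
conv_index_map <- function(in_shape) {
  nd <- length(in_shape)
  out_shape <- as.integer(ceiling(in_shape / 2))
  offs <- as.matrix(expand.grid(rep(list(0:2), nd)))
  Vout <- prod(out_shape)
  mult <- cumprod(c(1L, in_shape[-nd]))
  rep_each <- cumprod(c(1L, out_shape[-nd]))
  rep_times <- rev(cumprod(c(1L, rev(out_shape)[-nd])))
  idx <- matrix(0L, Vout, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    lin <- rep(0, Vout); ok <- rep(TRUE, Vout)
    for (a in seq_len(nd)) {
      co <- 2L * (0:(out_shape[a] - 1L)) + offs[k, a] - 1L
      va <- rep(rep(co, each = rep_each[a]), times = rep_times[a])
      ok <- ok & va >= 0L & va < in_shape[a]
      lin <- lin + va * mult[a]
    }
    idx[, k] <- as.integer(ifelse(ok, lin + 1L, 0L))
  }
  list(idx = idx, in_shape = in_shape, out_shape = out_shape,
       Vin = prod(in_shape), Vout = Vout, K = nrow(offs))
}

mat_scale_cols <- function(m, s) m * rep(s, each = nrow(m))

nn_bn_eps <- 1e-5

# Forward pass. X: (V0*B) x 1 activation matrix. Returns logits (length B)
# and, when `keep_cache`, everything backward needs, including updated
# batch-norm running stats (momentum 0.1) in training mode.
nn_forward <- function(model, X, B, training = FALSE, keep_cache = FALSE) {
  cache <- list(B = B, blocks = vector("list", length(model$geom)))
  bn_updates <- list()
  A <- X
  for (i in seq_along(model$geom)) {
    g <- model$geom[[i]]
    p <- model$par
    Xg <- dw_forward(A, g$idx, p[[paste0("dw_", i)]], B)
    Xp <- Xg %*% p[[paste0("pw_", i)]]
    if (training) {
      mu <- colMeans(Xp)
      va <- colMeans(Xp * Xp) - mu^2
      bn_updates[[paste0("bn_mean_", i)]] <-
        0.9 * model$bn[[paste0("bn_mean_", i)]] + 0.1 * mu
      bn_updates[[paste0("bn_var_", i)]] <-
        0.9 * model$bn[[paste0("bn_var_", i)]] + 0.1 * va
    } else {
      mu <- model$bn[[paste0("bn_mean_", i)]]
      va <- model$bn[[paste0("bn_var_", i)]]
    }
    invstd <- 1 / sqrt(va + nn_bn_eps)
    br <- bn_relu_forward(Xp, mu, invstd, p[[paste0("bn_gamma_", i)]],
                          p[[paste0("bn_beta_", i)]])
    if (keep_cache)
      cache$blocks[[i]] <- list(A_in = A, Xg = Xg, xhat = br$xhat,
                                invstd = invstd, A_out = br$A,
                                training = training)
    A <- br$A
  }
  # flatten: rows of A are (v within b); features ordered voxel-fastest,
  # then channel
  gl <- model$geom[[length(model$geom)]]
  V <- gl$Vout; C <- ncol(A)
  arr <- array(A, dim = c(V, B, C))
  Fm <- matrix(aperm(arr, c(1, 3, 2)), nrow = V * C, ncol = B)
  Fm <- t(Fm)
  H_pre <- sweep(Fm %*% model$par$fc1_W, 2, model$par$fc1_b, `+`)
  H <- pmax(H_pre, 0)
  logit <- as.numeric(H %*% model$par$fc2_W + model$par$fc2_b)
  if (keep_cache) {
    cache$Fm <- Fm; cache$H_pre <- H_pre; cache$H <- H
    cache$A_last <- A
  }
  list(logit = logit, cache = cache, bn_updates = bn_updates)
}

# Backward pass from d(loss)/d(logit). Returns parameter gradients and
# (optionally) the gradient with respect to the input activation matrix.
nn_backward <- function(model, cache, dlogit, want_input_grad = FALSE) {
  B <- cache$B
  grads <- list()
  dlogit <- matrix(dlogit, ncol = 1)
  grads$fc2_W <- t(cache$H) %*% dlogit
  grads$fc2_b <- sum(dlogit)
  dH <- dlogit %*% t(model$par$fc2_W)
  dH[cache$H_pre <= 0] <- 0
  grads$fc1_W <- t(cache$Fm) %*% dH
  grads$fc1_b <- colSums(dH)
  dF <- dH %*% t(model$par$fc1_W)
  gl <- model$geom[[length(model$geom)]]
  V <- gl$Vout; C <- length(model$par[[paste0("bn_gamma_",
                                              length(model$geom))]])
  arr <- array(t(dF), dim = c(V, C, B))
  dA <- array(aperm(arr, c(1, 3, 2)), dim = c(V * B, C))
  for (i in rev(seq_along(model$geom))) {
    g <- model$geom[[i]]
    bl <- cache$blocks[[i]]
    bb <- bn_relu_backward(dA, bl$A_out, bl$xhat,
                           model$par[[paste0("bn_gamma_", i)]],
                           bl$invstd, bl$training)
    grads[[paste0("bn_gamma_", i)]] <- bb$dgamma
    grads[[paste0("bn_beta_", i)]] <- bb$dbeta
    dXp <- bb$dXp
    grads[[paste0("pw_", i)]] <- t(bl$Xg) %*% dXp
    dXg <- dXp %*% t(model$par[[paste0("pw_", i)]])
    need_dx <- i > 1L || want_input_grad
    bk <- dw_backward(dXg, bl$A_in, g$idx, model$par[[paste0("dw_", i)]],
                      B, need_dx)
    grads[[paste0("dw_", i)]] <- bk$dW
    dA <- if (need_dx) bk$dX else NULL
  }
  list(grads = grads, dX = dA)
}

# One Adam step over all trainable parameters (in-place on the model list).
nn_adam_step <- function(model, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  decayed <- grepl("^(dw_|pw_)|^fc[12]_W$", names(model$par))
  for (j in seq_along(model$par)) {
    nm <- names(model$par)[j]
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    step <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && decayed[j])
      step <- step + weight_decay * model$par[[nm]]
    model$par[[nm]] <- model$par[[nm]] - lr * step
  }
  list(model = model, state = state)
}

# Numerically stable binary cross-entropy on logits; returns mean loss and
# d(loss)/d(logit).
nn_bce <- function(logit, y) {
  p <- 1 / (1 + exp(-logit))
  loss <- mean(ifelse(logit > 0,
                      log1p(exp(-logit)) + (1 - y) * logit,
                      log1p(exp(logit)) - y * logit))
  list(loss = loss, dlogit = (p - y) / length(y))
}

# Stack a list of equally shaped sample arrays into the batched activation
# matrix layout.
nn_input_matrix <- function(samples) {
  matrix(unlist(lapply(samples, as.vector), use.names = FALSE), ncol = 1)
}
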