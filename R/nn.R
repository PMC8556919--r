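## Minimal dense-network engine: forward pass, backpropagation and Adam for
## the base network (dense -> batch-norm -> ReLU [-> dropout] per hidden
## layer, linear dense output). Written in base R matrix code; there is no
## neural-network framework in the supported dependency stack, and the
## network is small enough (two hidden layers) that explicit backprop is
## both transparent and fast.

## broadcast a per-feature vector across the rows of an n x d matrix
bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

init_params <- function(cfg) {
  dims <- c(cfg$input_dim, cfg$hidden_dims, cfg$embedding_dim)
  H <- length(cfg$hidden_dims)
  params <- list()
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  for (i in seq_len(H)) {
    params[[paste0("W", i)]] <- glorot(dims[i], dims[i + 1])
    params[[paste0("b", i)]] <- numeric(dims[i + 1])
    params[[paste0("gamma", i)]] <- rep(1, dims[i + 1])
    params[[paste0("beta", i)]] <- numeric(dims[i + 1])
  }
  params$W_out <- glorot(dims[H + 1], cfg$embedding_dim)
  params$b_out <- numeric(cfg$embedding_dim)
  params
}

init_bn_stats <- function(cfg) {
  lapply(seq_along(cfg$hidden_dims), function(i)
    list(mean = numeric(cfg$hidden_dims[i]), var = rep(1, cfg$hidden_dims[i])))
}

## dropout applies to hidden layers with index >= cfg$dropout_from_layer
layer_has_dropout <- function(cfg, i) {
  cfg$dropout_rate > 0 && i >= cfg$dropout_from_layer
}

## Forward through the base network.
##  training: use batch statistics in batch-norm (and update running stats
##            when update_bn); otherwise use running statistics.
##  dropout_on: sample dropout masks (training or Monte-Carlo dropout).
## Returns list(E = embeddings, cache = per-layer intermediates).
forward_base <- function(params, bn_stats, cfg, X, training = FALSE,
                         dropout_on = training, update_bn = training,
                         keep_cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != cfg$input_dim)
    stop2("input has ", ncol(X), " features, model expects ", cfg$input_dim)
  H <- length(cfg$hidden_dims)
  n <- nrow(X)
  cache <- if (keep_cache) vector("list", H) else NULL
  A <- X
  ## per hidden layer: dense -> ReLU -> batch-norm -> (dropout)
  for (i in seq_len(H)) {
    W <- params[[paste0("W", i)]]
    Z <- A %*% W + bcast(params[[paste0("b", i)]], n)
    R <- pmax(Z, 0)                      # ReLU before normalization
    if (training) {
      mu <- colMeans(R)
      v <- colMeans(R * R) - mu * mu     # biased batch variance
      v <- pmax(v, 0)
      if (update_bn) {
        m <- cfg$bn_momentum
        bn_stats[[i]]$mean <- m * bn_stats[[i]]$mean + (1 - m) * mu
        bn_stats[[i]]$var <- m * bn_stats[[i]]$var + (1 - m) * v
      }
    } else {
      mu <- bn_stats[[i]]$mean
      v <- bn_stats[[i]]$var
    }
    ivar <- 1 / sqrt(v + cfg$bn_epsilon)
    xhat <- (R - bcast(mu, n)) * bcast(ivar, n)
    A_new <- xhat * bcast(params[[paste0("gamma", i)]], n) +
      bcast(params[[paste0("beta", i)]], n)
    mask <- NULL
    if (dropout_on && layer_has_dropout(cfg, i)) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(stats::rbinom(n * ncol(A_new), 1L, keep) / keep,
                     n, ncol(A_new))
      A_new <- A_new * mask
    }
    if (keep_cache)
      cache[[i]] <- list(A_in = A, Z = Z, xhat = xhat, ivar = ivar,
                         mask = mask)
    A <- A_new
  }
  E <- A %*% params$W_out + bcast(params$b_out, n)
  if (keep_cache) cache$A_last <- A
  list(E = E, cache = cache, bn_stats = bn_stats)
}

## Backprop dE (n x embedding_dim) through one branch; returns gradients
## named like params. Regularization gradients are added by the caller
## (once, not per branch).
backward_base <- function(params, cfg, cache, dE) {
  H <- length(cfg$hidden_dims)
  n <- nrow(dE)
  grads <- list()
  grads$W_out <- t(cache$A_last) %*% dE
  grads$b_out <- colSums(dE)
  dA <- dE %*% t(params$W_out)
  for (i in rev(seq_len(H))) {
    cc <- cache[[i]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dY <- dA                              # gradient at batch-norm output
    gamma <- params[[paste0("gamma", i)]]
    grads[[paste0("gamma", i)]] <- colSums(dY * cc$xhat)
    grads[[paste0("beta", i)]] <- colSums(dY)
    dxhat <- dY * bcast(gamma, n)
    ## batch-norm backward (batch statistics)
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * cc$xhat)
    dR <- (dxhat - bcast(mean_dxhat, n) - cc$xhat * bcast(mean_dxhat_xhat, n)) *
      bcast(cc$ivar, n)
    dZ <- dR * (cc$Z > 0)                 # ReLU backward
    grads[[paste0("W", i)]] <- t(cc$A_in) %*% dZ
    grads[[paste0("b", i)]] <- colSums(dZ)
    dA <- dZ %*% t(params[[paste0("W", i)]])
  }
  grads
}

add_grads <- function(g1, g2) {
  for (nm in names(g2)) g1[[nm]] <- (g1[[nm]] %||% 0) + g2[[nm]]
  g1
}

## L1/L2 penalty on the first dense layer's weights: value and gradient
reg_loss <- function(params, cfg) {
  cfg$l1_penalty * sum(abs(params$W1)) + cfg$l2_penalty * sum(params$W1^2)
}

add_reg_grad <- function(grads, params, cfg) {
  grads$W1 <- grads$W1 + cfg$l1_penalty * sign(params$W1) +
    2 * cfg$l2_penalty * params$W1
  grads
}

init_adam <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## rowwise cosine similarity of two embedding matrices
cosine_rows <- function(Ea, Eb) {
  na <- sqrt(rowSums(Ea * Ea))
  nb <- sqrt(rowSums(Eb * Eb))
  if (any(na == 0) || any(nb == 0)) stop2("zero-norm embedding in cosine head")
  rowSums(Ea * Eb) / (na * nb)
}

## Gradient of mean((cos(Ea, Eb) - t)^2) wrt both embedding matrices.
cosine_mse_grad <- function(Ea, Eb, target) {
  n <- nrow(Ea)
  na <- sqrt(rowSums(Ea * Ea))
  nb <- sqrt(rowSums(Eb * Eb))
  s <- rowSums(Ea * Eb) / (na * nb)
  ds <- 2 * (s - target) / n
  dEa <- (Eb / (na * nb) - Ea * (s / na^2)) * ds
  dEb <- (Ea / (na * nb) - Eb * (s / nb^2)) * ds
  list(loss = mean((s - target)^2), s = s, dEa = dEa, dEb = dEb)
}
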