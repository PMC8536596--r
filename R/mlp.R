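# Minimal multilayer perceptron with hand-written backpropagation.
#
# Architecture (per hidden layer): linear -> ReLU -> batch normalization
# (optional) -> dropout (optional), followed by a linear output layer that
# emits one logit per grid interval. A "bias-only" network ignores the
# covariates and holds a single trainable logit vector; it is the vehicle
# for closed-form maximum-likelihood checks. Training uses Adam on
# minibatches. All randomness (initialization, shuffling, dropout masks)
# flows from R's RNG, so runs are reproducible from a seed in
# single-threaded mode.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

mlp_init <- function(q, hidden, m, batch_norm = TRUE, bias_only = FALSE) {
  arch <- list(
    q = q, hidden = hidden, m = m,
    batch_norm = batch_norm, bias_only = bias_only
  )
  params <- list()
  bn_stats <- list()
  if (bias_only) {
    params$b_out <- numeric(m)
  } else {
    fan_in <- q
    for (l in seq_along(hidden)) {
      k <- hidden[l]
      # He initialization for ReLU layers
      params[[paste0("W", l)]] <- matrix(
        stats::rnorm(fan_in * k, 0, sqrt(2 / fan_in)), fan_in, k
      )
      params[[paste0("b", l)]] <- numeric(k)
      if (batch_norm) {
        params[[paste0("g", l)]] <- rep(1, k)
        params[[paste0("be", l)]] <- numeric(k)
        bn_stats[[paste0("mean", l)]] <- numeric(k)
        bn_stats[[paste0("var", l)]] <- rep(1, k)
      }
      fan_in <- k
    }
    params$W_out <- matrix(
      stats::rnorm(fan_in * m, 0, sqrt(1 / fan_in)), fan_in, m
    )
    params$b_out <- numeric(m)
  }
  list(arch = arch, params = params, bn_stats = bn_stats)
}

add_rows <- function(a, b) a + matrix(b, nrow(a), length(b), byrow = TRUE)

mlp_forward <- function(net, x, training = FALSE, dropout = 0) {
  p <- net$params
  arch <- net$arch
  if (arch$bias_only) {
    phi <- matrix(p$b_out, nrow(x), arch$m, byrow = TRUE)
    return(list(phi = phi, cache = list(n = nrow(x)), net = net))
  }
  z <- x
  cache <- list()
  for (l in seq_along(arch$hidden)) {
    a <- add_rows(z %*% p[[paste0("W", l)]], p[[paste0("b", l)]])
    r <- pmax(a, 0)
    lc <- list(z_in = z, relu_mask = a > 0)
    out <- r
    if (arch$batch_norm) {
      if (training) {
        mu <- colMeans(r)
        v <- colMeans(r^2) - mu^2 # biased batch variance
        net$bn_stats[[paste0("mean", l)]] <-
          (1 - BN_MOMENTUM) * net$bn_stats[[paste0("mean", l)]] + BN_MOMENTUM * mu
        net$bn_stats[[paste0("var", l)]] <-
          (1 - BN_MOMENTUM) * net$bn_stats[[paste0("var", l)]] + BN_MOMENTUM * v
      } else {
        mu <- net$bn_stats[[paste0("mean", l)]]
        v <- net$bn_stats[[paste0("var", l)]]
      }
      std <- sqrt(v + BN_EPS)
      xhat <- add_rows(r, -mu) / matrix(std, nrow(r), length(std), byrow = TRUE)
      out <- add_rows(
        xhat * matrix(p[[paste0("g", l)]], nrow(r), ncol(r), byrow = TRUE),
        p[[paste0("be", l)]]
      )
      lc$xhat <- xhat
      lc$std <- std
    }
    if (training && dropout > 0) {
      mask <- (matrix(stats::runif(length(out)), nrow(out)) >= dropout) / (1 - dropout)
      out <- out * mask
      lc$drop_mask <- mask
    }
    cache[[l]] <- lc
    z <- out
  }
  phi <- add_rows(z %*% p$W_out, p$b_out)
  cache$z_last <- z
  list(phi = phi, cache = cache, net = net)
}

mlp_backward <- function(net, cache, dphi) {
  p <- net$params
  arch <- net$arch
  grads <- list()
  if (arch$bias_only) {
    grads$b_out <- colSums(dphi)
    return(grads)
  }
  grads$W_out <- crossprod(cache$z_last, dphi)
  grads$b_out <- colSums(dphi)
  dz <- tcrossprod(dphi, p$W_out)
  for (l in rev(seq_along(arch$hidden))) {
    lc <- cache[[l]]
    if (!is.null(lc$drop_mask)) dz <- dz * lc$drop_mask
    if (arch$batch_norm) {
      g <- p[[paste0("g", l)]]
      grads[[paste0("g", l)]] <- colSums(dz * lc$xhat)
      grads[[paste0("be", l)]] <- colSums(dz)
      dxhat <- dz * matrix(g, nrow(dz), ncol(dz), byrow = TRUE)
      # batch-norm backward with biased batch variance
      mean_dxhat <- colMeans(dxhat)
      mean_dxhat_xhat <- colMeans(dxhat * lc$xhat)
      dz <- (add_rows(dxhat, -mean_dxhat) -
        lc$xhat * matrix(mean_dxhat_xhat, nrow(dz), ncol(dz), byrow = TRUE)) /
        matrix(lc$std, nrow(dz), ncol(dz), byrow = TRUE)
    }
    da <- dz * lc$relu_mask
    grads[[paste0("W", l)]] <- crossprod(lc$z_in, da)
    grads[[paste0("b", l)]] <- colSums(da)
    dz <- tcrossprod(da, p[[paste0("W", l)]])
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(x) x * 0),
    v = lapply(params, function(x) x * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
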