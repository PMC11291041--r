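# Small fully-connected network in plain vectorised R: ReLU hidden layers,
# optional inverted dropout and (scale/shift-free) batch normalisation,
# softplus output activation so interval hazards are non-negative, Adam
# updates. Sized for tabular cohorts (thousands of rows, tens of features),
# where R's BLAS-backed matrix products are entirely adequate.

relu <- function(x) pmax(x, 0)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -40), 40)))

nn_init <- function(sizes, seed) {
  # sizes: c(q, hidden..., m); He-normal weights, zero biases
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    bn_mean <- lapply(sizes[-c(1, length(sizes))], function(k) rep(0, k))
    bn_var <- lapply(sizes[-c(1, length(sizes))], function(k) rep(1, k))
    list(W = W, b = b, bn_mean = bn_mean, bn_var = bn_var, sizes = sizes)
  })
}

addv <- function(M, v) sweep(M, 2, v, "+")

# forward pass; training = TRUE stores caches for backprop and samples
# dropout masks (caller must be inside a seeded RNG context)
nn_forward <- function(params, X, dropout = 0, batch_norm = FALSE,
                       training = FALSE, bn_eps = 1e-5, bn_momentum = 0.9) {
  L <- length(params$W)
  cache <- list(A = vector("list", L + 1), Z = vector("list", L),
                Zn = vector("list", L), bn = vector("list", L),
                drop = vector("list", L))
  A <- X
  cache$A[[1]] <- A
  for (l in seq_len(L - 1)) {
    Z <- addv(A %*% params$W[[l]], params$b[[l]])
    cache$Z[[l]] <- Z
    if (batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(addv(Z, -mu)^2)
        params$bn_mean[[l]] <- bn_momentum * params$bn_mean[[l]] + (1 - bn_momentum) * mu
        params$bn_var[[l]] <- bn_momentum * params$bn_var[[l]] + (1 - bn_momentum) * v
      } else {
        mu <- params$bn_mean[[l]]
        v <- params$bn_var[[l]]
      }
      inv_sd <- 1 / sqrt(v + bn_eps)
      Zn <- sweep(addv(Z, -mu), 2, inv_sd, "*")
      cache$bn[[l]] <- list(inv_sd = inv_sd, Zn = Zn)
      Z <- Zn
    }
    A <- relu(Z)
    if (training && dropout > 0) {
      mask <- matrix(rbinom(length(A), 1, 1 - dropout), nrow(A)) / (1 - dropout)
      A <- A * mask
      cache$drop[[l]] <- mask
    }
    cache$A[[l + 1]] <- A
  }
  Zout <- addv(A %*% params$W[[L]], params$b[[L]])
  cache$Z[[L]] <- Zout
  lambda <- softplus(Zout)
  list(lambda = lambda, cache = cache, params = params)
}

# backprop of dL/dlambda through softplus, linear layers, (batch norm) and
# ReLU; returns gradients shaped like params$W / params$b
nn_backward <- function(params, cache, dlambda, dropout = 0,
                        batch_norm = FALSE) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- dlambda * sigmoid(cache$Z[[L]])
  for (l in rev(seq_len(L))) {
    A <- cache$A[[l]]
    gW[[l]] <- crossprod(A, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- dZ %*% t(params$W[[l]])
      if (dropout > 0 && !is.null(cache$drop[[l - 1]]))
        dA <- dA * cache$drop[[l - 1]]
      if (batch_norm) {
        bn <- cache$bn[[l - 1]]
        dZn <- dA * (bn$Zn > 0) # ReLU applied to normalised activations
        colm <- colMeans(dZn)
        colmz <- colMeans(dZn * bn$Zn)
        dZ <- sweep(dZn, 2, colm, "-") - sweep(bn$Zn, 2, colmz, "*")
        dZ <- sweep(dZ, 2, bn$inv_sd, "*")
      } else {
        dZ <- dA * (cache$Z[[l - 1]] > 0)
      }
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(params) {
  zero_like <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}
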