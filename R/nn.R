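# Neural-network primitives with explicit forward/backward passes.
#
# Layout conventions used throughout:
#   * "rows form":  R x T matrices whose rows are independent series; rows
#     are stacked trial-fastest, i.e. row r = n + N*(c-1) [+ N*C*(f-1)].
#   * "seq form":   F x T x N arrays for the attention/TCN stages (features
#     by time by trial).
# Every *_fwd returns list(out, cache); every *_bwd consumes the cache and
# the upstream gradient and returns the parameter and input gradients.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  l <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -l, l), dims)
}

elu <- function(x) {
  d <- dim(x)
  y <- elu_cpp(matrix(x, nrow = if (is.null(d)) 1L else d[1L]))
  if (is.null(d)) as.vector(y) else array(y, d)
}

# dy * d(elu)/dx given forward input x and output y
elu_bwd <- function(x, y, dy) {
  d <- dim(x)
  n1 <- if (is.null(d)) 1L else d[1L]
  g <- elu_grad_cpp(matrix(x, nrow = n1), matrix(y, nrow = n1),
                    matrix(dy, nrow = n1))
  if (is.null(d)) as.vector(g) else array(g, d)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- average pooling along time (columns), window p, remainder dropped ----
pool_fwd <- function(X, p) {
  T_in <- ncol(X)
  T_out <- T_in %/% p
  Xc <- X[, seq_len(p * T_out), drop = FALSE]
  out <- Xc %*% pool_mat(T_in, p)
  list(out = out, cache = list(p = p, T_in = T_in, T_out = T_out))
}

pool_mat <- function(T_in, p) {
  T_out <- T_in %/% p
  P <- matrix(0, p * T_out, T_out)
  P[cbind(seq_len(p * T_out), rep(seq_len(T_out), each = p))] <- 1 / p
  P
}

pool_bwd <- function(dOut, cache) {
  dX <- matrix(0, nrow(dOut), cache$T_in)
  idx <- seq_len(cache$p * cache$T_out)
  dX[, idx] <- dOut[, rep(seq_len(cache$T_out), each = cache$p)] / cache$p
  dX
}

# --- batch normalisation over contiguous row blocks (one block per map) ---
# X: (G*n_per) x T; gamma/beta length G. Per map g the statistics pool the
# whole block and all time steps. Compact-EEG-model settings: momentum 0.99
# (running <- 0.99 running + 0.01 batch), epsilon 1e-3.
bn_fwd <- function(X, gamma, beta, n_per, mode, state,
                   momentum = 0.99, eps = 1e-3) {
  G <- length(gamma)
  grp <- rep(seq_len(G), each = n_per)
  if (is.null(state)) state <- list(mean = numeric(G), var = rep(1, G))
  if (mode == "train") {
    m <- ncol(X) * n_per
    mu <- unname(rowsum(rowSums(X), grp)[, 1L]) / m
    xc <- X - mu[grp]
    va <- unname(rowsum(rowSums(xc * xc), grp)[, 1L]) / m
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
    xc <- X - mu[grp]
  }
  iv <- 1 / sqrt(va + eps)
  xhat <- xc * iv[grp]
  out <- xhat * gamma[grp] + beta[grp]
  list(out = out,
       cache = list(n_per = n_per, G = G, grp = grp, xhat = xhat, iv = iv,
                    mode = mode),
       state = state)
}

bn_bwd <- function(dOut, gamma, cache) {
  grp <- cache$grp
  xh <- cache$xhat
  dgamma <- unname(rowsum(rowSums(dOut * xh), grp)[, 1L])
  dbeta <- unname(rowsum(rowSums(dOut), grp)[, 1L])
  scale <- (gamma * cache$iv)[grp]
  if (cache$mode == "train") {
    m <- ncol(dOut) * cache$n_per
    dX <- scale * (dOut - dbeta[grp] / m - xh * dgamma[grp] / m)
  } else {
    dX <- scale * dOut
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- inverted dropout ------------------------------------------------------
dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- (array(stats::runif(length(X)), dim(X) %||% length(X)) >= rate) /
    (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dOut, cache) {
  if (is.null(cache)) dOut else dOut * cache
}

# --- layer normalisation over the feature axis of F x T x N ---------------
ln_fwd <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(X, d[1L])
  mu <- colMeans(Xm)
  xc <- sweep(Xm, 2L, mu)
  va <- colMeans(xc^2)
  iv <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, iv, `*`)
  out <- array(xh * gamma + beta, d)
  list(out = out, cache = list(xh = xh, iv = iv, d = d, gamma = gamma))
}

ln_bwd <- function(dOut, cache) {
  d <- cache$d
  Fdim <- d[1L]
  dy <- matrix(dOut, Fdim)
  xh <- cache$xh
  dgamma <- rowSums(dy * xh)
  dbeta <- rowSums(dy)
  dxh <- dy * cache$gamma
  dX <- sweep(dxh - matrix(colMeans(dxh), Fdim, ncol(dxh), byrow = TRUE) -
                xh * matrix(colMeans(dxh * xh), Fdim, ncol(xh), byrow = TRUE),
              2L, cache$iv, `*`)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# --- multi-head self-attention on F x T x N -------------------------------
# Projections Wq/Wk/Wv: F x (H*hd); Wo: (H*hd) x F; no biases. `mask` is an
# additive T x T matrix (0 / large-negative) applied to pre-softmax scores.
mha_fwd <- function(X, Wq, Wk, Wv, Wo, n_heads, head_dim, mask = NULL) {
  d <- dim(X); Fdim <- d[1L]; Tt <- d[2L]; N <- d[3L]
  Dh <- n_heads * head_dim
  out <- array(0, c(Fdim, Tt, N))
  cache <- list(Q = vector("list", N), K = vector("list", N),
                V = vector("list", N), A = vector("list", N),
                Hc = vector("list", N), X = X, mask = mask,
                n_heads = n_heads, head_dim = head_dim, d = d)
  sc <- 1 / sqrt(head_dim)
  for (n in seq_len(N)) {
    Xn <- X[, , n, drop = FALSE]; dim(Xn) <- c(Fdim, Tt)
    Q <- crossprod(Wq, Xn); K <- crossprod(Wk, Xn); V <- crossprod(Wv, Xn)
    A <- vector("list", n_heads)
    Hc <- matrix(0, Dh, Tt)
    for (h in seq_len(n_heads)) {
      rows <- ((h - 1L) * head_dim + 1L):(h * head_dim)
      S <- crossprod(Q[rows, , drop = FALSE], K[rows, , drop = FALSE]) * sc
      if (!is.null(mask)) S <- S + mask
      S <- S - apply(S, 1L, max)          # stabilised softmax over j (cols)
      E <- exp(S)
      Ah <- E / rowSums(E)
      A[[h]] <- Ah
      Hc[rows, ] <- V[rows, , drop = FALSE] %*% t(Ah)
    }
    out[, , n] <- crossprod(Wo, Hc)
    cache$Q[[n]] <- Q; cache$K[[n]] <- K; cache$V[[n]] <- V
    cache$A[[n]] <- A; cache$Hc[[n]] <- Hc
  }
  list(out = out, cache = cache)
}

mha_bwd <- function(dOut, Wq, Wk, Wv, Wo, cache) {
  d <- cache$d; Fdim <- d[1L]; Tt <- d[2L]; N <- d[3L]
  n_heads <- cache$n_heads; head_dim <- cache$head_dim
  sc <- 1 / sqrt(head_dim)
  dWq <- Wq * 0; dWk <- Wk * 0; dWv <- Wv * 0; dWo <- Wo * 0
  dX <- array(0, d)
  for (n in seq_len(N)) {
    Xn <- cache$X[, , n, drop = FALSE]; dim(Xn) <- c(Fdim, Tt)
    dOn <- dOut[, , n, drop = FALSE]; dim(dOn) <- c(Fdim, Tt)
    dWo <- dWo + cache$Hc[[n]] %*% t(dOn)
    dHc <- Wo %*% dOn
    Q <- cache$Q[[n]]; K <- cache$K[[n]]; V <- cache$V[[n]]
    dQ <- Q * 0; dK <- K * 0; dV <- V * 0
    for (h in seq_len(n_heads)) {
      rows <- ((h - 1L) * head_dim + 1L):(h * head_dim)
      Ah <- cache$A[[n]][[h]]
      dHh <- dHc[rows, , drop = FALSE]
      dA <- t(crossprod(V[rows, , drop = FALSE], dHh))   # T x T
      dV[rows, ] <- dHh %*% Ah
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[rows, ] <- K[rows, , drop = FALSE] %*% t(dS) * sc
      dK[rows, ] <- Q[rows, , drop = FALSE] %*% dS * sc
    }
    dWq <- dWq + Xn %*% t(dQ)
    dWk <- dWk + Xn %*% t(dK)
    dWv <- dWv + Xn %*% t(dV)
    dX[, , n] <- Wq %*% dQ + Wk %*% dK + Wv %*% dV
  }
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# --- causal dilated convolution on F x T x N ------------------------------
# W: F_out x F_in x K taps; tap k reads position t - (k-1)*dil (zero-padded
# history), so the output at t depends only on inputs at positions <= t.
causal_conv_fwd <- function(X, W, b, dil) {
  d <- dim(X); Fin <- d[1L]; Tt <- d[2L]; N <- d[3L]
  K <- dim(W)[3L]; Fout <- dim(W)[1L]
  out <- array(rep(b, times = Tt * N), c(Fout, Tt, N))
  shifts <- vector("list", K)
  for (k in seq_len(K)) {
    s <- (k - 1L) * dil
    Xs <- array(0, d)
    if (s < Tt) Xs[, (s + 1L):Tt, ] <- X[, seq_len(Tt - s), , drop = FALSE]
    shifts[[k]] <- matrix(Xs, Fin)
    out <- out + array(W[, , k] %*% shifts[[k]], c(Fout, Tt, N))
  }
  list(out = out, cache = list(shifts = shifts, d = d, K = K, dil = dil,
                               Fout = Fout))
}

causal_conv_bwd <- function(dOut, W, cache) {
  d <- cache$d; Tt <- d[2L]
  K <- cache$K; dil <- cache$dil
  dOm <- matrix(dOut, cache$Fout)
  dW <- W * 0
  db <- rowSums(dOm)
  dX <- array(0, d)
  for (k in seq_len(K)) {
    s <- (k - 1L) * dil
    dW[, , k] <- tcrossprod(dOm, cache$shifts[[k]])
    back <- array(crossprod(W[, , k], dOm), c(d[1L], Tt, d[3L]))
    if (s < Tt)
      dX[, seq_len(Tt - s), ] <- dX[, seq_len(Tt - s), , drop = FALSE] +
        back[, (s + 1L):Tt, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# --- softmax / cross-entropy ----------------------------------------------
softmax_cols <- function(L) {
  L <- sweep(L, 2L, apply(L, 2L, max))
  E <- exp(L)
  sweep(E, 2L, colSums(E), `/`)
}

# --- Adam ------------------------------------------------------------------
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# layout conversions ---------------------------------------------------------
# rows form (N*F rows, map-major blocks) <-> seq form F x T x N
rows_to_seq <- function(X, N, Fdim) {
  Tt <- ncol(X)
  aperm(array(X, c(N, Fdim, Tt)), c(2L, 3L, 1L))
}

seq_to_rows <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(3L, 1L, 2L)), d[3L] * d[1L], d[2L])
}
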