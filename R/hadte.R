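# HADTE block: residual efficient channel attention, locally masked
# multi-head self-attention, global (pre-layer-norm) multi-head
# self-attention, and a causal dilated TCN ending in the last-position
# feature vector.

MASK_NEG <- -1e9

#' HADTE block hyperparameters
#'
#' Defaults are the architecture's standard operating point: local attention window
#' `w = 16` with dilation `d = 1`, two heads of dimension 8 (the 32-dim
#' features are projected to 16 for Q/K/V and back to 32 on output so the
#' residual adds in feature space), ECA kernel 3 (the adaptive ECA rule at
#' 32 maps), and a two-block causal TCN with kernel 4, dilations 1 and 2,
#' ELU and dropout 0.3.
#'
#' @param w Local attention window size (time steps).
#' @param d Dilation rate of the window.
#' @param n_heads Number of attention heads.
#' @param head_dim Dimension per head.
#' @param eca_kernel ECA 1-D convolution kernel (odd).
#' @param tcn_blocks Number of residual TCN blocks (dilations 1, 2, 4, ...).
#' @param tcn_kernel TCN kernel length (>= 2).
#' @param tcn_dropout Dropout inside TCN blocks.
#' @return A `hadte_config` list.
#' @export
hadte_config <- function(w = 16L, d = 1L, n_heads = 2L, head_dim = 8L,
                         eca_kernel = 3L, tcn_blocks = 2L, tcn_kernel = 4L,
                         tcn_dropout = 0.3) {
  if (w < 1L || d < 1L) stop("window and dilation must be >= 1")
  if (eca_kernel %% 2L == 0L) stop("eca_kernel must be odd")
  structure(list(w = as.integer(w), d = as.integer(d),
                 n_heads = as.integer(n_heads), head_dim = as.integer(head_dim),
                 eca_kernel = as.integer(eca_kernel),
                 tcn_blocks = as.integer(tcn_blocks),
                 tcn_kernel = as.integer(tcn_kernel),
                 tcn_dropout = tcn_dropout),
            class = "hadte_config")
}

#' Additive local attention mask
#'
#' `M_ij = 0` iff `|i - j| <= w * d`, else a large negative sentinel
#' standing in for minus infinity, added to pre-softmax attention scores.
#' The mask is symmetric with a zero diagonal; `w >= T' - 1` leaves the
#' whole matrix unmasked.
#'
#' @param T_len Sequence length `T'` (>= 1).
#' @param w Window size (>= 0; 0 keeps only the diagonal).
#' @param d Dilation rate (>= 1).
#' @return `T_len` x `T_len` additive mask matrix.
#' @export
build_local_mask <- function(T_len, w, d = 1L) {
  if (!is.numeric(T_len) || length(T_len) != 1L || T_len < 1L)
    stop("sequence length must be a positive integer")
  if (w < 0L || d < 1L) stop("need w >= 0 and d >= 1")
  idx <- seq_len(T_len)
  M <- matrix(MASK_NEG, T_len, T_len)
  M[abs(outer(idx, idx, `-`)) <= w * d] <- 0
  M
}

# batched residual ECA on F x T x N ----------------------------------------
eca_fwd_batch <- function(H, w) {
  d <- dim(H); Fdim <- d[1L]; Tt <- d[2L]; N <- d[3L]
  K <- length(w); pad <- (K - 1L) %/% 2L
  s <- apply(H, c(1L, 3L), mean)               # F x N map descriptor
  sp <- rbind(matrix(0, pad, N), s, matrix(0, K - 1L - pad, N))
  cv <- matrix(0, Fdim, N)
  for (k in seq_len(K)) cv <- cv + w[k] * sp[k:(k + Fdim - 1L), , drop = FALSE]
  g <- sigmoid(cv)
  garr <- aperm(array(g, c(Fdim, N, Tt)), c(1L, 3L, 2L))
  out <- H * (1 + garr)
  list(out = out,
       cache = list(H = H, s = s, sp = sp, g = g, garr = garr, pad = pad,
                    K = K, d = d))
}

eca_bwd_batch <- function(dOut, w, cache) {
  d <- cache$d; Fdim <- d[1L]; Tt <- d[2L]; N <- d[3L]
  dH <- dOut * (1 + cache$garr)
  dg <- apply(dOut * cache$H, c(1L, 3L), sum)          # F x N
  dc <- dg * cache$g * (1 - cache$g)
  K <- cache$K; pad <- cache$pad
  dw <- numeric(K)
  dsp <- cache$sp * 0
  for (k in seq_len(K)) {
    rows <- k:(k + Fdim - 1L)
    dw[k] <- sum(dc * cache$sp[rows, , drop = FALSE])
    dsp[rows, ] <- dsp[rows, , drop = FALSE] + w[k] * dc
  }
  ds <- dsp[(pad + 1L):(pad + Fdim), , drop = FALSE]
  dH <- dH + aperm(array(ds / Tt, c(Fdim, N, Tt)), c(1L, 3L, 2L))
  list(dX = dH, dw = dw)
}

#' Residual efficient channel attention
#'
#' `F_eca = F + ECA(F)`: the feature-map descriptor (global average over
#' time) is filtered by a short 1-D convolution across neighbouring maps,
#' squashed by a sigmoid, and the gated copy of the input is added back on
#' the residual path. With zero convolution weights the gate is 0.5
#' everywhere and the output is exactly `1.5 F`.
#'
#' @param F_in Feature matrix, time x maps.
#' @param conv_weights Numeric vector of odd length (the ECA kernel).
#' @return Matrix of the same shape.
#' @export
residual_eca <- function(F_in, conv_weights) {
  if (length(conv_weights) %% 2L == 0L) stop("ECA kernel must be odd")
  F_in <- as.matrix(F_in)
  H <- array(t(F_in), c(ncol(F_in), nrow(F_in), 1L))
  t(eca_fwd_batch(H, conv_weights)$out[, , 1L])
}

# attention parameter bundles -----------------------------------------------
init_mha_params <- function(Fdim, n_heads, head_dim) {
  Dh <- n_heads * head_dim
  if (Dh > Fdim)
    stop(sprintf("attention inner dimension %d exceeds feature dimension %d",
                 Dh, Fdim))
  list(Wq = glorot(Fdim, Dh), Wk = glorot(Fdim, Dh), Wv = glorot(Fdim, Dh),
       Wo = glorot(Dh, Fdim))
}

#' Locally masked multi-head self-attention
#'
#' Two-head self-attention whose pre-softmax scores receive the additive
#' local mask, plus a residual connection: `F_local = MHA(F, F, F; M) + F`.
#' Attention rows are probability vectors supported only on unmasked
#' positions. The layer takes its input raw (no layer norm), matching the
#' local stage's definition.
#'
#' @param F_in Feature matrix, time x maps.
#' @param mask Additive mask from [build_local_mask()] of matching length.
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo`.
#' @param cfg A [hadte_config()].
#' @return Matrix time x maps, with per-head attention matrices in
#'   attribute `"attention"`.
#' @export
local_masked_attention <- function(F_in, mask, params, cfg = hadte_config()) {
  F_in <- as.matrix(F_in)
  Tt <- nrow(F_in)
  if (!all(dim(mask) == Tt))
    stop(sprintf("mask is %dx%d but the sequence length is %d",
                 nrow(mask), ncol(mask), Tt))
  if (any(apply(mask, 1L, function(r) all(r <= MASK_NEG / 2))))
    stop("mask has a fully masked row; attention cannot be normalised")
  X <- array(t(F_in), c(ncol(F_in), Tt, 1L))
  at <- mha_fwd(X, params$Wq, params$Wk, params$Wv, params$Wo,
                cfg$n_heads, cfg$head_dim, mask)
  out <- F_in + t(at$out[, , 1L])
  attr(out, "attention") <- at$cache$A[[1L]]
  out
}

#' Global multi-head self-attention with pre-layer-norm
#'
#' `F_global = MHA(LN(F), LN(F), LN(F)) + F`: the input is layer-normalised
#' before the attention projections and the residual adds the raw input.
#' There is no positional encoding; temporal order is carried by the
#' convolutional stages, which makes this stage permutation-equivariant.
#'
#' @param F_in Feature matrix, time x maps.
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo`, `ln_gamma`, `ln_beta`.
#' @param cfg A [hadte_config()].
#' @return Matrix time x maps.
#' @export
global_attention <- function(F_in, params, cfg = hadte_config()) {
  F_in <- as.matrix(F_in)
  X <- array(t(F_in), c(ncol(F_in), nrow(F_in), 1L))
  l <- ln_fwd(X, params$ln_gamma, params$ln_beta)
  at <- mha_fwd(l$out, params$Wq, params$Wk, params$Wv, params$Wo,
                cfg$n_heads, cfg$head_dim, NULL)
  F_in + t(at$out[, , 1L])
}

# batched TCN ---------------------------------------------------------------
tcn_fwd_batch <- function(H, params, cfg, mode) {
  if (cfg$tcn_kernel < 2L) stop("TCN kernel must be >= 2")
  caches <- vector("list", cfg$tcn_blocks)
  X <- H
  for (b in seq_len(cfg$tcn_blocks)) {
    dil <- 2L^(b - 1L)
    c1 <- causal_conv_fwd(X, params[[sprintf("tcn%d_W1", b)]],
                          params[[sprintf("tcn%d_b1", b)]], dil)
    e1 <- elu(c1$out)
    d1 <- dropout_fwd(e1, cfg$tcn_dropout, mode)
    c2 <- causal_conv_fwd(d1$out, params[[sprintf("tcn%d_W2", b)]],
                          params[[sprintf("tcn%d_b2", b)]], dil)
    e2 <- elu(c2$out)
    d2 <- dropout_fwd(e2, cfg$tcn_dropout, mode)
    out <- X + d2$out
    caches[[b]] <- list(X = X, c1 = c1$cache, c1out = c1$out, e1 = e1,
                        d1 = d1$cache, c2 = c2$cache, c2out = c2$out,
                        e2 = e2, d2 = d2$cache)
    X <- out
  }
  list(out = X, cache = caches)
}

tcn_bwd_batch <- function(dOut, params, cfg, caches) {
  g <- list()
  dX <- dOut
  for (b in rev(seq_len(cfg$tcn_blocks))) {
    cb <- caches[[b]]
    dbr <- dropout_bwd(dX, cb$d2)
    dc2 <- elu_bwd(cb$c2out, cb$e2, dbr)
    b2 <- causal_conv_bwd(dc2, params[[sprintf("tcn%d_W2", b)]], cb$c2)
    g[[sprintf("tcn%d_W2", b)]] <- b2$dW
    g[[sprintf("tcn%d_b2", b)]] <- b2$db
    dd1 <- dropout_bwd(b2$dX, cb$d1)
    dc1 <- elu_bwd(cb$c1out, cb$e1, dd1)
    b1 <- causal_conv_bwd(dc1, params[[sprintf("tcn%d_W1", b)]], cb$c1)
    g[[sprintf("tcn%d_W1", b)]] <- b1$dW
    g[[sprintf("tcn%d_b1", b)]] <- b1$db
    dX <- dX + b1$dX          # residual path
  }
  list(dX = dX, grads = g)
}

#' Causal dilated TCN over a feature sequence
#'
#' A stack of residual blocks (dilations 1, 2, 4, ...), each holding two
#' causal dilated convolutions with ELU and dropout. Causality: the output
#' at position t depends only on positions <= t. The deep representation is
#' the feature vector at the final position.
#'
#' @param F_in Feature matrix, time x maps.
#' @param params TCN parameters (see [init_hadte_params()]).
#' @param cfg A [hadte_config()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @param return_sequence Return the full time x maps output instead of the
#'   last-position vector.
#' @return Numeric vector of length `maps` (or a matrix if
#'   `return_sequence`).
#' @export
tcn_forward <- function(F_in, params, cfg = hadte_config(), mode = "eval",
                        return_sequence = FALSE) {
  F_in <- as.matrix(F_in)
  H <- array(t(F_in), c(ncol(F_in), nrow(F_in), 1L))
  out <- tcn_fwd_batch(H, params, cfg, mode)$out
  if (return_sequence) t(out[, , 1L]) else out[, nrow(F_in), 1L]
}

#' Full HADTE block on one trial
#'
#' Residual ECA, locally masked attention, global attention, then the TCN,
#' in order; each stage can be bypassed with an identity by naming it in
#' `flags` (the ablation wiring). With all three attention stages bypassed
#' the TCN sees `F_GATE` unchanged; with `"hadte"` in `flags` the whole
#' block is an identity and the last-position feature vector of the input
#' is returned.
#'
#' @param F_gate Feature matrix, time x maps (the GATE output).
#' @param params Parameters from [init_hadte_params()].
#' @param cfg A [hadte_config()].
#' @param mode `"eval"` or `"train"`.
#' @param flags Character subset of
#'   `c("residual_eca", "local_mha", "global_mha", "hadte")`.
#' @return Feature vector of length `maps`.
#' @export
hadte_forward <- function(F_gate, params, cfg = hadte_config(),
                          mode = "eval", flags = character(0)) {
  F_gate <- as.matrix(F_gate)
  if ("hadte" %in% flags) return(F_gate[nrow(F_gate), ])
  H <- F_gate
  if (!("residual_eca" %in% flags))
    H <- residual_eca(H, params$eca_w)
  if (!("local_mha" %in% flags)) {
    mask <- build_local_mask(nrow(H), cfg$w, cfg$d)
    H <- local_masked_attention(H, mask, params$loc, cfg)
  }
  if (!("global_mha" %in% flags))
    H <- global_attention(H, params$glob, cfg)
  tcn_forward(H, params, cfg, mode)
}

#' Initialise HADTE parameters
#'
#' @param cfg A [hadte_config()].
#' @param Fdim Feature dimension of the incoming sequence.
#' @return Named list: `eca_w`, attention bundles `loc` and `glob` (the
#'   latter with layer-norm gain/bias), and TCN block weights
#'   `tcn<b>_W1/b1/W2/b2` shaped maps x maps x kernel.
#' @export
init_hadte_params <- function(cfg, Fdim) {
  p <- list(eca_w = stats::rnorm(cfg$eca_kernel, 0, 0.1),
            loc = init_mha_params(Fdim, cfg$n_heads, cfg$head_dim),
            glob = c(init_mha_params(Fdim, cfg$n_heads, cfg$head_dim),
                     list(ln_gamma = rep(1, Fdim), ln_beta = rep(0, Fdim))))
  for (b in seq_len(cfg$tcn_blocks)) {
    p[[sprintf("tcn%d_W1", b)]] <- glorot(Fdim * cfg$tcn_kernel, Fdim,
                                          c(Fdim, Fdim, cfg$tcn_kernel))
    p[[sprintf("tcn%d_b1", b)]] <- rep(0, Fdim)
    p[[sprintf("tcn%d_W2", b)]] <- glorot(Fdim * cfg$tcn_kernel, Fdim,
                                          c(Fdim, Fdim, cfg$tcn_kernel))
    p[[sprintf("tcn%d_b2", b)]] <- rep(0, Fdim)
  }
  p
}
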