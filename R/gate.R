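# GATE block: Chebyshev graph convolution per time step, squeeze-and-
# excitation channel attention over electrodes, and the three-stage
# temporal-spatial convolutional encoder producing F_GATE.
#
# The exported functions take single trials in the natural time x electrodes
# orientation; the *_batch internals operate on the layouts described in
# nn.R and carry caches for backpropagation.

#' GATE block hyperparameters
#'
#' Defaults are the architecture's standard operating point: Chebyshev order `K = 3`,
#' `F1 = 16` temporal filters of length `kt = 64`, depth multiplier 2 giving
#' `F2 = 32` maps, average pooling by 8 then `P = 7`, a length-16 long
#' temporal convolution, dropout 0.3 and SE reduction ratio 4.
#'
#' @param K Chebyshev polynomial order.
#' @param F1 Temporal filter count of the first convolution.
#' @param kt Temporal kernel length of the first convolution.
#' @param depth_multiplier Spatial filters per temporal map.
#' @param F2 Output map count; must equal `F1 * depth_multiplier`.
#' @param pool1 First average-pooling window (samples).
#' @param pool2 Second average-pooling window (samples).
#' @param long_kernel Length of the third-stage temporal kernel.
#' @param dropout_rate Dropout after the encoder.
#' @param se_reduction SE bottleneck reduction ratio.
#' @return A `gate_config` list.
#' @export
gate_config <- function(K = 3L, F1 = 16L, kt = 64L, depth_multiplier = 2L,
                        F2 = F1 * depth_multiplier, pool1 = 8L, pool2 = 7L,
                        long_kernel = 16L, dropout_rate = 0.3,
                        se_reduction = 4L) {
  cfg <- list(K = as.integer(K), F1 = as.integer(F1), kt = as.integer(kt),
              depth_multiplier = as.integer(depth_multiplier),
              F2 = as.integer(F2), pool1 = as.integer(pool1),
              pool2 = as.integer(pool2), long_kernel = as.integer(long_kernel),
              dropout_rate = dropout_rate, se_reduction = as.integer(se_reduction))
  if (cfg$F2 != cfg$F1 * cfg$depth_multiplier)
    stop("F2 must equal F1 * depth_multiplier")
  if (any(unlist(cfg[c("K", "F1", "kt", "depth_multiplier", "pool1", "pool2",
                       "long_kernel")]) < 1L))
    stop("all GATE sizes must be >= 1")
  structure(cfg, class = "gate_config")
}

#' Chebyshev graph convolution of a trial
#'
#' Applies `Z_t = sum_k w_k T_k(A_hat) X_t` independently at every time
#' step, with one scalar weight per polynomial order (one input and one
#' output graph-feature map, so the electrode axis is preserved).
#'
#' @param X Trial matrix, time x electrodes.
#' @param graph A [spatial_graph()] whose electrode count matches `X`.
#' @param W Numeric vector of `K` order weights.
#' @return Filtered trial, time x electrodes.
#' @export
cheb_graph_conv <- function(X, graph, W) {
  X <- as.matrix(X)
  basis <- graph$cheb_basis
  if (is.null(basis)) stop("graph carries no Chebyshev basis; use spatial_graph()")
  if (ncol(X) != nrow(graph$A))
    stop(sprintf("trial has %d electrodes but graph has %d",
                 ncol(X), nrow(graph$A)))
  W <- unlist(W)
  if (length(W) != length(basis))
    stop(sprintf("expected %d order weights, got %d", length(basis), length(W)))
  S <- cheb_filter(basis, W)
  X %*% t(S)
}

cheb_filter <- function(basis, w) {
  S <- w[1L] * basis[[1L]]
  for (k in seq_along(basis)[-1L]) S <- S + w[k] * basis[[k]]
  S
}

#' Squeeze-and-excitation channel attention over electrodes
#'
#' Squeezes each electrode to its temporal average, passes the descriptor
#' through a two-layer bottleneck (`ReLU` then `sigmoid`), and rescales the
#' trial electrode-wise: `Z' = Z (.) sigmoid(W2 ReLU(W1 s))`. Every gate lies
#' in (0, 1), so the output never exceeds the input in magnitude.
#'
#' @param Z Trial matrix, time x electrodes.
#' @param weights List with `W1` (hidden x electrodes) and `W2`
#'   (electrodes x hidden).
#' @return Gated trial with the per-electrode gate attached as attribute
#'   `"gate"`.
#' @export
se_channel_attention <- function(Z, weights) {
  Z <- as.matrix(Z)
  s <- colMeans(Z)
  h <- pmax(as.vector(weights$W1 %*% s), 0)
  g <- sigmoid(as.vector(weights$W2 %*% h))
  out <- sweep(Z, 2L, g, `*`)
  attr(out, "gate") <- g
  out
}

# batched graph convolution ------------------------------------------------
gc_fwd_batch <- function(X, graph, w) {
  d <- dim(X)                      # N x C x T
  S <- cheb_filter(graph$cheb_basis, w)
  Xm <- matrix(aperm(X, c(2L, 1L, 3L)), d[2L])      # C x (N*T)
  Zm <- S %*% Xm
  list(out = Zm, cache = list(Xm = Xm, S = S, basis = graph$cheb_basis, d = d))
}

gc_bwd_batch <- function(dZm, cache) {
  dS <- tcrossprod(dZm, cache$Xm)
  dw <- vapply(cache$basis, function(Tk) sum(Tk * dS), numeric(1L))
  dXm <- crossprod(cache$S, dZm)
  dX <- aperm(array(dXm, c(cache$d[2L], cache$d[1L], cache$d[3L])),
              c(2L, 1L, 3L))
  list(dX = dX, dw = dw)
}

# C x (N*T) electrode-major form  ->  (N*C) x T rows form
zm_to_rows <- function(Zm, N) {
  C <- nrow(Zm)
  Tt <- ncol(Zm) %/% N
  matrix(aperm(array(Zm, c(C, N, Tt)), c(2L, 1L, 3L)), N * C, Tt)
}

rows_to_zm <- function(Zr, N) {
  C <- nrow(Zr) %/% N
  Tt <- ncol(Zr)
  matrix(aperm(array(Zr, c(N, C, Tt)), c(2L, 1L, 3L)), C, N * Tt)
}

# batched SE over electrodes (rows form) ------------------------------------
se_fwd_batch <- function(Zr, W1, W2, N, C) {
  Tt <- ncol(Zr)
  s <- matrix(rowMeans(Zr), N, C)
  A1 <- s %*% t(W1)
  H <- pmax(A1, 0)
  g <- sigmoid(H %*% t(W2))        # N x C
  gv <- as.vector(g)
  out <- Zr * gv
  list(out = out, cache = list(Zr = Zr, s = s, A1 = A1, H = H, g = g,
                               gv = gv, N = N, C = C, Tt = Tt))
}

se_bwd_batch <- function(dOut, W1, W2, cache) {
  dZr <- dOut * cache$gv
  dg <- matrix(rowSums(dOut * cache$Zr), cache$N, cache$C)
  dA2 <- dg * cache$g * (1 - cache$g)
  dW2 <- t(dA2) %*% cache$H
  dH <- dA2 %*% W2
  dA1 <- dH * (cache$A1 > 0)
  dW1 <- t(dA1) %*% cache$s
  ds <- dA1 %*% W1
  dZr <- dZr + as.vector(ds) / cache$Tt
  list(dX = dZr, dW1 = dW1, dW2 = dW2)
}

# map mixing: (N*F) x T rows form through a F_out x F_in matrix ------------
mix_fwd <- function(X, N, Fin, W) {
  Tt <- ncol(X)
  Xm <- matrix(aperm(array(X, c(N, Fin, Tt)), c(2L, 1L, 3L)), Fin)
  Y <- W %*% Xm
  out <- matrix(aperm(array(Y, c(nrow(W), N, Tt)), c(2L, 1L, 3L)),
                N * nrow(W), Tt)
  list(out = out, cache = list(Xm = Xm, N = N, Fin = Fin, Tt = Tt,
                               Fout = nrow(W)))
}

mix_bwd <- function(dOut, W, cache) {
  dY <- matrix(aperm(array(dOut, c(cache$N, cache$Fout, cache$Tt)),
                     c(2L, 1L, 3L)), cache$Fout)
  dW <- tcrossprod(dY, cache$Xm)
  dXm <- crossprod(W, dY)
  dX <- matrix(aperm(array(dXm, c(cache$Fin, cache$N, cache$Tt)),
                     c(2L, 1L, 3L)), cache$N * cache$Fin, cache$Tt)
  list(dX = dX, dW = dW)
}

# temporal-spatial encoder, batched (rows form in, rows form out) ----------
tse_fwd_batch <- function(Zr, params, cfg, N, C, mode, state) {
  Tt <- ncol(Zr)
  if (Tt < cfg$kt)
    stop(sprintf("time length %d is shorter than the temporal kernel %d",
                 Tt, cfg$kt))
  cache <- list(N = N, C = C, cfg = cfg)
  if (is.null(state)) state <- list(bn1 = NULL, bn2 = NULL, bn3 = NULL)

  # stage 1: shared temporal filters per electrode + BN
  pl1 <- (cfg$kt - 1L) %/% 2L
  H1 <- conv1d_rows_fwd(Zr, params$conv1_W, pl1)
  cache$Zr <- Zr; cache$pl1 <- pl1
  b1 <- bn_fwd(H1, params$bn1_gamma, params$bn1_beta, N * C, mode, state$bn1)
  state$bn1 <- b1$state
  cache$H1 <- H1; cache$b1 <- b1$cache

  # stage 2: depthwise spatial convolution spanning all C electrodes
  dm <- cfg$depth_multiplier
  H2 <- matrix(0, N * cfg$F2, Tt)
  cache$s2 <- vector("list", cfg$F1)
  for (f1 in seq_len(cfg$F1)) {
    rows <- ((f1 - 1L) * N * C + 1L):(f1 * N * C)
    Xf <- matrix(aperm(array(b1$out[rows, ], c(N, C, Tt)), c(2L, 1L, 3L)), C)
    Wf <- matrix(params$dw_W[, , f1], dm, C)
    Yf <- Wf %*% Xf                                  # dm x (N*T)
    for (m in seq_len(dm))
      H2[(( (f1 - 1L) * dm + m - 1L) * N + 1L):(((f1 - 1L) * dm + m) * N), ] <-
        matrix(Yf[m, ], N, Tt)
    cache$s2[[f1]] <- Xf
  }
  b2 <- bn_fwd(H2, params$bn2_gamma, params$bn2_beta, N, mode, state$bn2)
  state$bn2 <- b2$state
  E2 <- elu(b2$out)
  p1 <- pool_fwd(E2, cfg$pool1)
  cache$H2 <- H2; cache$b2 <- b2$cache; cache$bn2in <- b2$out
  cache$E2 <- E2; cache$p1 <- p1$cache

  # stage 3: separable long temporal convolution (depthwise + pointwise)
  pl3 <- (cfg$long_kernel - 1L) %/% 2L
  H3d <- conv1d_depthwise_fwd(p1$out, params$sep_Wd, N, pl3)
  mx <- mix_fwd(H3d, N, cfg$F2, params$sep_Wp)
  b3 <- bn_fwd(mx$out, params$bn3_gamma, params$bn3_beta, N, mode, state$bn3)
  state$bn3 <- b3$state
  E3 <- elu(b3$out)
  p2 <- pool_fwd(E3, cfg$pool2)
  dr <- dropout_fwd(p2$out, cfg$dropout_rate, mode)
  cache$p1out <- p1$out; cache$pl3 <- pl3; cache$H3d <- H3d
  cache$mx <- mx$cache; cache$b3 <- b3$cache; cache$bn3in <- b3$out
  cache$E3 <- E3; cache$p2 <- p2$cache; cache$dr <- dr$cache

  list(out = dr$out, cache = cache, state = state)
}

tse_bwd_batch <- function(dOut, params, cache) {
  cfg <- cache$cfg; N <- cache$N; C <- cache$C
  g <- list()

  dp2 <- dropout_bwd(dOut, cache$dr)
  dE3 <- pool_bwd(dp2, cache$p2)
  db3in <- elu_bwd(cache$bn3in, cache$E3, dE3)
  b3 <- bn_bwd(db3in, params$bn3_gamma, cache$b3)
  g$bn3_gamma <- b3$dgamma; g$bn3_beta <- b3$dbeta
  mx <- mix_bwd(b3$dX, params$sep_Wp, cache$mx)
  g$sep_Wp <- mx$dW
  d3 <- conv1d_depthwise_bwd(cache$p1out, params$sep_Wd, mx$dX, N, cache$pl3)
  g$sep_Wd <- d3$dW
  dE2 <- pool_bwd(d3$dX, cache$p1)
  db2in <- elu_bwd(cache$bn2in, cache$E2, dE2)
  b2 <- bn_bwd(db2in, params$bn2_gamma, cache$b2)
  g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta

  dm <- cfg$depth_multiplier
  Tt <- ncol(cache$Zr)
  dH1bn <- matrix(0, cfg$F1 * N * C, Tt)
  g$dw_W <- params$dw_W * 0
  for (f1 in seq_len(cfg$F1)) {
    dYf <- matrix(0, dm, N * Tt)
    for (m in seq_len(dm)) {
      j <- (f1 - 1L) * dm + m
      dYf[m, ] <- as.vector(b2$dX[((j - 1L) * N + 1L):(j * N), ])
    }
    g$dw_W[, , f1] <- tcrossprod(dYf, cache$s2[[f1]])
    dXf <- crossprod(matrix(params$dw_W[, , f1], dm, C), dYf)  # C x (N*T)
    rows <- ((f1 - 1L) * N * C + 1L):(f1 * N * C)
    dH1bn[rows, ] <- matrix(aperm(array(dXf, c(C, N, Tt)), c(2L, 1L, 3L)),
                            N * C, Tt)
  }
  b1 <- bn_bwd(dH1bn, params$bn1_gamma, cache$b1)
  g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
  c1 <- conv1d_rows_bwd(cache$Zr, params$conv1_W, b1$dX, cache$pl1)
  g$conv1_W <- c1$dW
  list(dX = c1$dX, grads = g)
}

#' Temporal-spatial convolutional encoding of a trial
#'
#' The three-stage encoder: (1) length-`kt` temporal convolution with `F1`
#' shared filters per electrode plus batch normalisation; (2) depthwise
#' spatial convolution spanning all electrodes (multiplier 2, `F2` maps),
#' batch normalisation, ELU, and average pooling by `pool1`; (3) a
#' length-`long_kernel` separable temporal convolution, batch normalisation,
#' ELU, average pooling by `pool2`, and dropout. The output time length is
#' `floor(floor(T / pool1) / pool2)`.
#'
#' @param Z Trial matrix, time x electrodes (typically the SE-gated graph
#'   features).
#' @param params Parameter list from [init_gate_params()].
#' @param cfg A [gate_config()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return `F_GATE`: matrix, `T'` x `F2`.
#' @export
temporal_spatial_encode <- function(Z, params, cfg = gate_config(),
                                    mode = "eval") {
  Z <- as.matrix(Z)
  out <- tse_fwd_batch(t(Z), params, cfg, N = 1L, C = ncol(Z), mode = mode,
                       state = NULL)
  t(out$out)
}

#' Full GATE block on one trial
#'
#' Graph convolution, SE channel attention (optionally bypassed, which is
#' the "without channel attention" ablation wiring), then the
#' temporal-spatial encoder.
#'
#' @param X Trial matrix, time x electrodes.
#' @param graph A [spatial_graph()].
#' @param params Parameters from [init_gate_params()].
#' @param cfg A [gate_config()].
#' @param mode `"eval"` or `"train"`.
#' @param use_channel_attention Set `FALSE` to bypass SE (`Z' = Z`).
#' @return `F_GATE` matrix, `T'` x `F2`.
#' @export
gate_forward <- function(X, graph, params, cfg = gate_config(),
                         mode = "eval", use_channel_attention = TRUE) {
  Z <- cheb_graph_conv(X, graph, params$cheb_w)
  Zp <- if (use_channel_attention)
    se_channel_attention(Z, list(W1 = params$se_W1, W2 = params$se_W2))
  else Z
  temporal_spatial_encode(Zp, params, cfg, mode)
}

#' Initialise GATE parameters
#'
#' Glorot-uniform weights for all convolutions and the SE bottleneck; the
#' Chebyshev order weights start at the identity filter (w_0 = 1) plus small
#' noise so the graph stage begins near a pass-through; batch-norm scales
#' start at 1 and shifts at 0.
#'
#' @param cfg A [gate_config()].
#' @param C Electrode count.
#' @return Named list of parameter arrays.
#' @export
init_gate_params <- function(cfg, C) {
  h <- max(1L, C %/% cfg$se_reduction)
  list(cheb_w = c(1, stats::rnorm(cfg$K - 1L, 0, 0.1)),
       se_W1 = glorot(C, h, c(h, C)),
       se_W2 = glorot(h, C, c(C, h)),
       conv1_W = glorot(cfg$kt, cfg$F1, c(cfg$F1, cfg$kt)),
       bn1_gamma = rep(1, cfg$F1), bn1_beta = rep(0, cfg$F1),
       dw_W = glorot(C, cfg$depth_multiplier,
                     c(cfg$depth_multiplier, C, cfg$F1)),
       bn2_gamma = rep(1, cfg$F2), bn2_beta = rep(0, cfg$F2),
       sep_Wd = glorot(cfg$long_kernel, 1, c(cfg$F2, cfg$long_kernel)),
       sep_Wp = glorot(cfg$F2, cfg$F2, c(cfg$F2, cfg$F2)),
       bn3_gamma = rep(1, cfg$F2), bn3_beta = rep(0, cfg$F2))
}

#' Output sequence length of the GATE encoder
#' @param T_in Input time samples.
#' @param cfg A [gate_config()].
#' @return `floor(floor(T_in / pool1) / pool2)`.
#' @export
gate_out_len <- function(T_in, cfg = gate_config()) {
  (T_in %/% cfg$pool1) %/% cfg$pool2
}
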