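test_that("local mask census matches exhaustive enumeration", {
  # spec geometry: 20 steps, window 16, dilation 1
  M <- build_local_mask(20L, 16L, 1L)
  expect_equal(sum(M == 0), 388L)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 0))

  expect_equal(sum(build_local_mask(20L, 19L, 1L) != 0), 0L)  # full window
  expect_equal(sum(build_local_mask(20L, 0L, 1L) == 0), 20L)  # diagonal only
  expect_error(build_local_mask(0L, 16L), "positive")

  # bandwidth property against direct |i-j| enumeration, dilation included
  set.seed(11)
  for (i in 1:20) {
    Tn <- sample(2:64, 1L); w <- sample(0:8, 1L); dd <- sample(1:3, 1L)
    M <- build_local_mask(Tn, w, dd)
    ref <- abs(outer(seq_len(Tn), seq_len(Tn), `-`)) <= w * dd
    expect_identical(M == 0, ref)
    expect_true(isSymmetric(M))
  }
})

test_that("residual ECA follows its closed form", {
  set.seed(12)
  F_in <- matrix(rnorm(10 * 6), 10L, 6L)
  expect_equal(residual_eca(F_in, c(0, 0, 0)), 1.5 * F_in)
  expect_error(residual_eca(F_in, c(0.1, 0.2)), "odd")

  w <- rnorm(3)
  out <- residual_eca(F_in, w)
  gate <- (out - F_in) / F_in
  expect_true(all(gate > 0 & gate < 1))
  # explicit GAP -> conv1d -> sigmoid -> scale -> add oracle
  s <- colMeans(F_in)
  sp <- c(0, s, 0)
  cv <- vapply(seq_along(s), function(f) sum(w * sp[f:(f + 2L)]), numeric(1L))
  g <- 1 / (1 + exp(-cv))
  expect_equal(out, F_in + sweep(F_in, 2L, g, `*`), tolerance = 1e-12)
})

test_that("masked attention is residual, normalised, and mask-supported", {
  cfg <- tiny_hadte_cfg()
  set.seed(13)
  Tn <- 9L; Fd <- 6L
  F_in <- matrix(rnorm(Tn * Fd), Tn, Fd)
  p <- gahtnet:::init_mha_params(Fd, cfg$n_heads, cfg$head_dim)
  mask <- build_local_mask(Tn, 2L, 1L)

  pz <- p; pz$Wv <- pz$Wv * 0
  expect_equal(unname(local_masked_attention(F_in, mask, pz, cfg)[, ]), F_in,
               ignore_attr = TRUE)

  out <- local_masked_attention(F_in, mask, p, cfg)
  A <- attr(out, "attention")
  for (Ah in A) {
    expect_equal(rowSums(Ah), rep(1, Tn), tolerance = 1e-12)
    expect_true(all(Ah[mask != 0] < 1e-12))
    expect_true(all(Ah >= 0))
  }

  expect_error(local_masked_attention(F_in, build_local_mask(5L, 2L), p, cfg),
               "sequence length")
  all_blocked <- matrix(gahtnet:::MASK_NEG, Tn, Tn)
  expect_error(local_masked_attention(F_in, all_blocked, p, cfg),
               "fully masked")
})

test_that("a full window makes local attention equal unmasked attention", {
  cfg <- tiny_hadte_cfg()
  set.seed(14)
  Tn <- 8L; Fd <- 6L
  F_in <- matrix(rnorm(Tn * Fd), Tn, Fd)
  p <- gahtnet:::init_mha_params(Fd, cfg$n_heads, cfg$head_dim)
  wide <- local_masked_attention(F_in, build_local_mask(Tn, Tn, 1L), p, cfg)
  X <- array(t(F_in), c(Fd, Tn, 1L))
  unmasked <- F_in + t(gahtnet:::mha_fwd(X, p$Wq, p$Wk, p$Wv, p$Wo,
                                         cfg$n_heads, cfg$head_dim,
                                         NULL)$out[, , 1L])
  expect_equal(unname(wide[, ]), unmasked, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("global attention is residual, normalised and permutation-equivariant", {
  cfg <- tiny_hadte_cfg()
  set.seed(15)
  Tn <- 7L; Fd <- 6L
  F_in <- matrix(rnorm(Tn * Fd), Tn, Fd)
  p <- c(gahtnet:::init_mha_params(Fd, cfg$n_heads, cfg$head_dim),
         list(ln_gamma = rep(1, Fd), ln_beta = rep(0, Fd)))

  pz <- p; pz$Wv <- pz$Wv * 0
  expect_equal(global_attention(F_in, pz, cfg), F_in)

  # layer norm: per-position mean 0, variance 1 before gain/bias
  l <- gahtnet:::ln_fwd(array(t(F_in), c(Fd, Tn, 1L)), rep(1, Fd), rep(0, Fd))
  m <- matrix(l$out, Fd)
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_lt(max(abs(colMeans(m^2) - 1)), 1e-4)   # eps-regularised variance

  # no positional encoding: permuting time permutes the output identically
  perm <- sample(Tn)
  expect_equal(global_attention(F_in[perm, ], p, cfg),
               global_attention(F_in, p, cfg)[perm, ], tolerance = 1e-10)
})

test_that("TCN is causal, deterministic in eval, and matches a hand loop", {
  cfg <- hadte_config(w = 3L, n_heads = 1L, head_dim = 2L,
                      tcn_blocks = 1L, tcn_kernel = 2L, tcn_dropout = 0)
  set.seed(16)
  Fd <- 3L
  p <- init_hadte_params(cfg, Fd)

  # causality: perturbations after position t never reach position <= t
  for (i in 1:100) {
    x1 <- matrix(rnorm(8L * Fd), 8L, Fd)
    cut <- sample(2:7, 1L)
    x2 <- x1
    x2[(cut + 1L):8L, ] <- rnorm((8L - cut) * Fd)
    o1 <- tcn_forward(x1, p, cfg, return_sequence = TRUE)
    o2 <- tcn_forward(x2, p, cfg, return_sequence = TRUE)
    expect_equal(o1[1:cut, ], o2[1:cut, ], tolerance = 1e-12)
  }

  # explicit convolution loop oracle, single block, kernel 2, dilation 1
  x <- matrix(rnorm(4L * Fd), 4L, Fd)
  out <- tcn_forward(x, p, cfg, return_sequence = TRUE)
  W1 <- p$tcn1_W1; b1 <- p$tcn1_b1
  W2 <- p$tcn1_W2; b2 <- p$tcn1_b2
  elu_ref <- function(v) ifelse(v > 0, v, exp(v) - 1)
  conv_ref <- function(xm, W, b) {
    t(sapply(1:4, function(t) {
      prev <- if (t == 1L) rep(0, Fd) else xm[t - 1L, ]
      W[, , 1L] %*% xm[t, ] + W[, , 2L] %*% prev + b
    }))
  }
  h <- elu_ref(conv_ref(x, W1, b1))
  branch <- elu_ref(conv_ref(h, W2, b2))
  expect_equal(out, x + branch, tolerance = 1e-10)

  expect_equal(tcn_forward(x, p, cfg), tcn_forward(x, p, cfg))
  expect_error(tcn_forward(x, p, hadte_config(n_heads = 1L, head_dim = 2L,
                                              tcn_kernel = 1L)), ">= 2")
})

test_that("hadte_forward composes stages and honours bypass flags", {
  cfg <- tiny_hadte_cfg()
  set.seed(17)
  Fg <- matrix(rnorm(20L * 6L), 20L, 6L)
  p <- init_hadte_params(cfg, 6L)

  v <- hadte_forward(Fg, p, cfg)
  expect_length(v, 6L)
  expect_true(all(is.finite(v)))

  # full bypass: identity, last position of F_GATE
  expect_equal(hadte_forward(Fg, p, cfg, flags = "hadte"), Fg[20L, ])

  # both attention stages bypassed: ECA feeds the TCN directly
  both_off <- hadte_forward(Fg, p, cfg,
                            flags = c("local_mha", "global_mha"))
  expect_equal(both_off,
               tcn_forward(residual_eca(Fg, p$eca_w), p, cfg))

  # full-size geometry: (20 x 32) -> 32-vector
  cfg32 <- hadte_config(tcn_dropout = 0)
  p32 <- init_hadte_params(cfg32, 32L)
  v32 <- hadte_forward(matrix(rnorm(20L * 32L), 20L, 32L), p32, cfg32)
  expect_length(v32, 32L)
})
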