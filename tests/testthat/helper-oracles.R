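# Independent oracles and tiny shared fixtures for the test suite.

# Brute-force Delaunay edge set: a triangle belongs to the triangulation iff
# its circumcircle contains no other point strictly inside; its edges are
# Delaunay edges. Independent of any shipped edge list.
bf_delaunay_edges <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  edges <- matrix(0L, 0L, 2L)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    p1 <- pts[a, ]; p2 <- pts[b, ]; p3 <- pts[cc, ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
             sum(p3^2) * (p1[2] - p2[2])) / d
    uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
             sum(p3^2) * (p2[1] - p1[1])) / d
    r <- sqrt((p1[1] - ux)^2 + (p1[2] - uy)^2)
    dd <- sqrt((pts[, 1] - ux)^2 + (pts[, 2] - uy)^2)
    if (any(dd[-c(a, b, cc)] < r - tol)) next
    edges <- rbind(edges, c(a, b), c(a, cc), c(b, cc))
  }
  unique(edges)
}

# random connected-ish symmetric binary adjacency with unit diagonal
random_adjacency <- function(C, p = 0.5) {
  A <- matrix(0, C, C)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A <- A + t(A)
  diag(A) <- 1
  A
}

# naive per-time-step Chebyshev graph convolution (loop oracle)
naive_cheb_conv <- function(X, basis, w) {
  out <- X * 0
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    zt <- 0 * xt
    for (k in seq_along(basis)) zt <- zt + w[k] * (basis[[k]] %*% xt)
    out[t, ] <- zt
  }
  out
}

# small in-memory recording with cue events
make_test_recording <- function(fs = 250, dur_s = 30, channels = 3L,
                                cues = c(2.0, 8.0, 14.0, 20.0),
                                codes = c(1L, 2L, 1L, 2L), seed = 99L) {
  set.seed(seed)
  n <- as.integer(fs * dur_s)
  structure(list(signal = matrix(stats::rnorm(channels * n), channels, n),
                 fs = fs,
                 events = data.frame(sample = as.integer(round(cues * fs)),
                                     code = codes),
                 channel_names = paste0("ch", seq_len(channels))),
            class = "raw_recording")
}

# shrunken network configurations so unit tests run in seconds
tiny_gate_cfg <- function() {
  gate_config(K = 3L, F1 = 4L, kt = 16L, depth_multiplier = 2L, pool1 = 4L,
              pool2 = 2L, long_kernel = 4L, dropout_rate = 0,
              se_reduction = 2L)
}

tiny_hadte_cfg <- function() {
  hadte_config(w = 3L, d = 1L, n_heads = 2L, head_dim = 2L, eca_kernel = 3L,
               tcn_blocks = 2L, tcn_kernel = 3L, tcn_dropout = 0)
}

tiny_model <- function(n_classes = 2L, T_in = 80L, seed = 7L) {
  graph <- spatial_graph(montage_2b())
  cfg <- model_config(n_classes = n_classes, n_electrodes = 3L,
                      gate = tiny_gate_cfg(), hadte = tiny_hadte_cfg(),
                      input_samples = T_in)
  build_model(cfg, graph, seed = seed)
}

tiny_trials <- function(n_per_class = 12L, T_in = 80L, seed = 5L,
                        separation = 2) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- array(stats::rnorm(n * 3L * T_in), c(n, 3L, T_in))
  y <- rep(0:1, each = n_per_class)
  tgrid <- seq_len(T_in) / 50
  for (i in seq_len(n)) {
    amp <- if (y[i] == 0) separation else 0.2
    X[i, 1L, ] <- X[i, 1L, ] + amp * sin(2 * pi * 10 * tgrid)
  }
  trial_set(X, y, fs = 50, channel_names = c("C3", "Cz", "C4"))
}

# nearest-centroid fit closure on oracle band-power features, usable with
# run_protocol (fits on train labels, predicts test)
centroid_fitter <- function(erd_map) {
  force(erd_map)
  function(train_ts) {
    ftr <- gahtnet:::oracle_features(train_ts, erd_map)
    cents <- lapply(sort(unique(train_ts$labels)), function(k)
      colMeans(ftr[train_ts$labels == k, , drop = FALSE]))
    function(test_ts) {
      fte <- gahtnet:::oracle_features(test_ts, erd_map)
      d <- sapply(cents, function(ce) rowSums(sweep(fte, 2L, ce)^2))
      apply(as.matrix(d), 1L, which.min) - 1L
    }
  }
}
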