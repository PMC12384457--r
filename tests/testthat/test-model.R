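test_that("model builds are deterministic and ablations shed parameters", {
  graph <- spatial_graph(montage_2a())
  cfg <- model_config(n_classes = 4L, n_electrodes = 22L)
  m1 <- build_model(cfg, graph, seed = 1L)
  m2 <- build_model(cfg, graph, seed = 1L)
  expect_equal(n_params(m1), n_params(m2))
  expect_equal(m1$params, m2$params)

  full <- n_params(m1)
  for (flag in gahtnet:::ABLATION_FLAGS) {
    mv <- build_model(ablate_variant(cfg, flag), graph, seed = 1L)
    expect_lt(n_params(mv), full)
  }
})

test_that("configuration validation catches inconsistencies", {
  graph <- spatial_graph(montage_2b())
  expect_error(model_config(n_classes = 1L, n_electrodes = 3L), "two classes")
  expect_error(model_config(4L, 22L, ablation = "bogus"),
               "bogus.*valid flags")
  expect_error(build_model(model_config(4L, 22L), graph), "electrodes")
  expect_error(ablate_variant(model_config(4L, 22L), "nope"), "valid flags")
  cfg <- ablate_variant(model_config(4L, 22L), "hadte")
  expect_equal(ablate_variant(cfg, "hadte")$ablation, "hadte")  # idempotent
})

test_that("probabilities normalise and the loss obeys its closed forms", {
  sm <- gahtnet:::softmax_cols
  expect_equal(as.vector(sm(matrix(c(0, 0, 0, 0)))), rep(0.25, 4L))
  expect_equal(as.vector(sm(matrix(c(1, 2)))), c(0.2689414, 0.7310586),
               tolerance = 1e-6)
  L <- matrix(rnorm(8), 4L)
  expect_equal(sm(L + 3.7), sm(L), tolerance = 1e-12)   # shift invariance

  expect_equal(cross_entropy(diag(4L)[c(1, 3), ], c(0L, 2L)), 0)
  expect_equal(cross_entropy(matrix(0.25, 2L, 4L), c(0L, 3L)), log(4))
  p1 <- matrix(c(0.9, 0.1), 1L); p2 <- matrix(c(0.3, 0.7), 1L)
  a <- cross_entropy(p1, 0L); b <- cross_entropy(p2, 0L)
  expect_equal(cross_entropy(rbind(p1, p2), c(0L, 0L)), (a + b) / 2)
  expect_true(is.finite(cross_entropy(matrix(c(0, 1), 1L), 0L)))

  model <- tiny_model()
  X0 <- array(0, c(3L, 3L, 80L))
  pr <- predict_proba(model, X0)
  expect_true(all(is.finite(pr)))
  expect_equal(rowSums(pr), rep(1, 3L), tolerance = 1e-6)
  expect_error(predict_proba(model, array(0, c(2L, 3L, 40L))), "input must be")
})

test_that("analytic gradients match finite differences on a tiny model", {
  model <- tiny_model(seed = 7L)
  set.seed(42)
  N <- 4L
  X <- array(rnorm(N * 3L * 80L), c(N, 3L, 80L))
  y <- c(0L, 1L, 0L, 1L)
  loss_fn <- function(m) {
    fw <- gahtnet:::model_forward(m, X, "train")
    pr <- gahtnet:::softmax_cols(fw$logits)
    mean(-log(pmax(pr[cbind(y + 1L, seq_along(y))], 1e-12)))
  }
  fw <- gahtnet:::model_forward(model, X, "train")
  pr <- gahtnet:::softmax_cols(fw$logits)
  dl <- pr
  dl[cbind(y + 1L, seq_along(y))] <- dl[cbind(y + 1L, seq_along(y))] - 1
  dl <- dl / N
  grads <- gahtnet:::model_backward(model, fw$cache, dl)
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (ii in sample(length(p), min(2L, length(p)))) {
      mp <- model; mp$params[[nm]][ii] <- p[ii] + eps
      mm <- model; mm$params[[nm]][ii] <- p[ii] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("training is seeded-deterministic and learns separable data", {
  ts <- tiny_trials(n_per_class = 16L, separation = 3)
  model <- tiny_model(seed = 9L)
  tcfg <- train_config(batch_size = 8L, max_epochs = 6L, patience = 6L,
                       seed = 11L, val_fraction = 0.25)
  f1 <- train_model(tiny_model(seed = 9L), ts, tcfg)
  f2 <- train_model(tiny_model(seed = 9L), ts, tcfg)
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history$train_loss, 1L), f1$history$train_loss[1L])
  expect_gt(tail(f1$history$train_acc, 1L), 0.6)
})

test_that("early stopping halts after patience exhausts and restores weights", {
  ts <- tiny_trials(n_per_class = 6L)
  tcfg <- train_config(lr = 0, batch_size = 8L, max_epochs = 50L,
                       patience = 1L, seed = 3L, val_fraction = 0.25)
  fit <- train_model(tiny_model(), ts, tcfg)
  # lr 0: the metric never improves after epoch 1, patience 1 stops at 2
  expect_equal(attr(fit$history, "stopped_epoch"), 2L)
  expect_equal(attr(fit$history, "best_epoch"), 1L)
  expect_equal(nrow(fit$history), 2L)
})

test_that("single-class training sets are rejected", {
  ts <- tiny_trials(n_per_class = 6L)
  one <- trials_subset(ts, which(ts$labels == 0L))
  expect_error(train_model(tiny_model(), one), "two classes")
})

test_that("every ablation variant trains a step without error", {
  graph <- spatial_graph(montage_2b())
  ts <- tiny_trials(n_per_class = 8L)
  variants <- c(list(character(0)),
                as.list(gahtnet:::ABLATION_FLAGS[
                  gahtnet:::ABLATION_FLAGS != "ts_encoder"]),
                list(c("local_mha", "global_mha")))
  for (fl in variants) {
    cfg <- model_config(2L, 3L, gate = tiny_gate_cfg(),
                        hadte = tiny_hadte_cfg(), input_samples = 80L,
                        ablation = fl)
    m <- build_model(cfg, graph, seed = 2L)
    fit <- train_model(m, ts, train_config(batch_size = 8L, max_epochs = 1L,
                                           patience = 1L, seed = 2L,
                                           val_fraction = 0.25))
    pr <- predict_proba(fit$model, ts)
    expect_true(all(is.finite(pr)))
    expect_equal(rowSums(pr), rep(1, dim(ts)[1L]), tolerance = 1e-6)
  }
  # the encoder bypass needs head geometry that fits the electrode count;
  # on the 22-electrode montage the stock heads fit
  graph22 <- spatial_graph(montage_2a())
  set.seed(30)
  ts22 <- trial_set(array(rnorm(8 * 22 * 224), c(8L, 22L, 224L)),
                    rep(0:1, 4L), fs = 250)
  cfg22 <- model_config(2L, 22L, gate = gate_config(dropout_rate = 0),
                        hadte = hadte_config(tcn_dropout = 0),
                        input_samples = 224L, ablation = "ts_encoder")
  m22 <- build_model(cfg22, graph22, seed = 2L)
  expect_equal(m22$feature_dim, 22L)
  pr <- predict_proba(m22, ts22)
  expect_equal(rowSums(pr), rep(1, 8L), tolerance = 1e-6)
})

test_that("hadte bypass feeds the last GATE step straight to the classifier", {
  graph <- spatial_graph(montage_2b())
  cfg <- model_config(2L, 3L, gate = tiny_gate_cfg(),
                      hadte = tiny_hadte_cfg(), input_samples = 80L,
                      ablation = "hadte")
  m <- build_model(cfg, graph, seed = 4L)
  set.seed(5)
  X <- array(rnorm(2 * 3 * 80), c(2L, 3L, 80L))
  emb <- model_embeddings(m, X)
  fg <- gate_forward(t(X[1L, , ]), graph,
                     c(m$params, init_gate_params(tiny_gate_cfg(), 3L)[0]),
                     tiny_gate_cfg())
  expect_equal(emb[1L, ], unname(fg[nrow(fg), ]), tolerance = 1e-10)
})

test_that("checkpoints round-trip the trained state", {
  model <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params)
  set.seed(6)
  X <- array(rnorm(2 * 3 * 80), c(2L, 3L, 80L))
  expect_equal(predict_proba(back, X), predict_proba(model, X))
})
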