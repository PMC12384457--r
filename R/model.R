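# GAH-TNet assembly: GATE -> HADTE -> classifier, with the training loop
# (Adam, stratified validation holdout, early stopping) and the ablation
# switchboard.

ABLATION_FLAGS <- c("channel_attention", "ts_encoder", "residual_eca",
                    "local_mha", "global_mha", "hadte")

#' Model configuration
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_electrodes Electrode count (must match the graph).
#' @param gate A [gate_config()].
#' @param hadte A [hadte_config()].
#' @param input_samples Samples per trial (1125 at 250 Hz for the 4.5 s
#'   cue-locked window).
#' @param ablation Character subset of the ablation flags
#'   (`r paste(ABLATION_FLAGS, collapse = ", ")`).
#' @return A `model_config`.
#' @export
model_config <- function(n_classes, n_electrodes, gate = gate_config(),
                         hadte = hadte_config(), input_samples = 1125L,
                         ablation = character(0)) {
  if (n_classes < 2L) stop("need at least two classes")
  bad <- setdiff(ablation, ABLATION_FLAGS)
  if (length(bad) > 0L)
    stop(sprintf("unknown ablation flag(s) %s; valid flags are: %s",
                 paste(bad, collapse = ", "),
                 paste(ABLATION_FLAGS, collapse = ", ")))
  structure(list(gate = gate, hadte = hadte,
                 n_classes = as.integer(n_classes),
                 n_electrodes = as.integer(n_electrodes),
                 input_samples = as.integer(input_samples),
                 ablation = unique(ablation)),
            class = "model_config")
}

#' Derive an ablated model variant
#'
#' Returns the configuration with the named stage bypassed; applying the
#' same flag twice is idempotent (set semantics). The seven ablation
#' variants of the architecture are: without channel attention, without the
#' temporal-spatial encoder, without residual ECA, without local masked
#' attention, without global attention, without both attention stages, and
#' without the whole HADTE block.
#'
#' @param cfg A [model_config()].
#' @param flag One of the ablation flags, or a character vector of them.
#' @return The modified `model_config`.
#' @export
ablate_variant <- function(cfg, flag) {
  bad <- setdiff(flag, ABLATION_FLAGS)
  if (length(bad) > 0L)
    stop(sprintf("unknown ablation flag(s) %s; valid flags are: %s",
                 paste(bad, collapse = ", "),
                 paste(ABLATION_FLAGS, collapse = ", ")))
  cfg$ablation <- unique(c(cfg$ablation, flag))
  cfg
}

#' Training configuration
#'
#' Defaults follow the architecture's standard training schedule: Adam with initial learning rate
#' 0.001, batch size 64, up to 1000 epochs with early-stopping patience 300.
#' The monitored quantity is accuracy on a stratified holdout of
#' `val_fraction` of the training trials (monitoring test data would leak);
#' the best-epoch weights are restored after stopping.
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed controlling shuffling, initialisation order and
#'   dropout.
#' @param val_fraction Fraction of training trials held out for monitoring,
#'   in (0, 0.5).
#' @return A `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 64L, max_epochs = 1000L,
                         patience = 300L, seed = 1L, val_fraction = 0.2) {
  if (patience > max_epochs) stop("patience must not exceed max_epochs")
  if (val_fraction <= 0 || val_fraction >= 0.5)
    stop("val_fraction must lie in (0, 0.5)")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 val_fraction = val_fraction),
            class = "train_config")
}

model_feature_dim <- function(cfg) {
  if ("ts_encoder" %in% cfg$ablation) cfg$n_electrodes else cfg$gate$F2
}

model_t_prime <- function(cfg) {
  # the bypass adapter pools by pool1*pool2 so both paths share T'
  (cfg$input_samples %/% cfg$gate$pool1) %/% cfg$gate$pool2
}

#' Build a GAH-TNet model
#'
#' Initialises all parameters for the configured (possibly ablated)
#' architecture. The forward pass maps a (batch x electrodes x samples)
#' array to (batch x classes) probabilities. Parameter shapes are a
#' deterministic function of the configuration; each ablation flag removes
#' its stage's parameters entirely.
#'
#' @param cfg A [model_config()].
#' @param graph A [spatial_graph()] whose electrode count matches the
#'   configuration.
#' @param seed Integer seed for weight initialisation.
#' @return A `gahtnet_model`.
#' @export
build_model <- function(cfg, graph, seed = 1L) {
  if (nrow(graph$A) != cfg$n_electrodes)
    stop(sprintf("graph has %d electrodes but the config declares %d",
                 nrow(graph$A), cfg$n_electrodes))
  if (length(graph$cheb_basis) != cfg$gate$K)
    stop("graph Chebyshev order differs from the GATE configuration")
  ab <- cfg$ablation
  Fdim <- model_feature_dim(cfg)
  set.seed(seed)
  C <- cfg$n_electrodes
  p <- list(cheb_w = c(1, stats::rnorm(cfg$gate$K - 1L, 0, 0.1)))
  if (!("channel_attention" %in% ab)) {
    h <- max(1L, C %/% cfg$gate$se_reduction)
    p$se_W1 <- glorot(C, h, c(h, C))
    p$se_W2 <- glorot(h, C, c(C, h))
  }
  if (!("ts_encoder" %in% ab)) {
    gp <- init_gate_params(cfg$gate, C)
    p <- c(p, gp[setdiff(names(gp), c("cheb_w", "se_W1", "se_W2"))])
  }
  hd <- cfg$hadte
  if (!("hadte" %in% ab)) {
    if (!("residual_eca" %in% ab)) p$eca_w <- stats::rnorm(hd$eca_kernel, 0, 0.1)
    if (!("local_mha" %in% ab)) {
      lp <- init_mha_params(Fdim, hd$n_heads, hd$head_dim)
      names(lp) <- paste0("loc_", names(lp))
      p <- c(p, lp)
    }
    if (!("global_mha" %in% ab)) {
      gp <- init_mha_params(Fdim, hd$n_heads, hd$head_dim)
      names(gp) <- paste0("glob_", names(gp))
      p <- c(p, gp, list(ln_gamma = rep(1, Fdim), ln_beta = rep(0, Fdim)))
    }
    for (b in seq_len(hd$tcn_blocks)) {
      p[[sprintf("tcn%d_W1", b)]] <- glorot(Fdim * hd$tcn_kernel, Fdim,
                                            c(Fdim, Fdim, hd$tcn_kernel))
      p[[sprintf("tcn%d_b1", b)]] <- rep(0, Fdim)
      p[[sprintf("tcn%d_W2", b)]] <- glorot(Fdim * hd$tcn_kernel, Fdim,
                                            c(Fdim, Fdim, hd$tcn_kernel))
      p[[sprintf("tcn%d_b2", b)]] <- rep(0, Fdim)
    }
  }
  p$fc_W <- glorot(Fdim, cfg$n_classes)
  p$fc_b <- rep(0, cfg$n_classes)
  structure(list(cfg = cfg, graph = graph, params = p, bn_state = NULL,
                 feature_dim = Fdim, t_prime = model_t_prime(cfg)),
            class = "gahtnet_model")
}

#' @export
print.gahtnet_model <- function(x, ...) {
  cat(sprintf("<gahtnet_model> %d electrodes -> %d classes, %d parameters\n",
              x$cfg$n_electrodes, x$cfg$n_classes, n_params(x)))
  if (length(x$cfg$ablation) > 0L)
    cat("  ablated:", paste(x$cfg$ablation, collapse = ", "), "\n")
  invisible(x)
}

#' Total trainable parameter count
#' @param model A `gahtnet_model`.
#' @return Integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

# full forward pass ----------------------------------------------------------
model_forward <- function(model, X, mode = "eval") {
  cfg <- model$cfg; p <- model$params; ab <- cfg$ablation
  d <- dim(X)
  if (length(d) != 3L || d[2L] != cfg$n_electrodes || d[3L] != cfg$input_samples)
    stop(sprintf("input must be batch x %d x %d; got %s",
                 cfg$n_electrodes, cfg$input_samples,
                 paste(d, collapse = " x ")))
  N <- d[1L]; C <- d[2L]
  cache <- list(N = N, C = C)
  state <- model$bn_state

  gc <- gc_fwd_batch(X, model$graph, p$cheb_w)
  Zr <- zm_to_rows(gc$out, N)
  cache$gc <- gc$cache

  if (!("channel_attention" %in% ab)) {
    se <- se_fwd_batch(Zr, p$se_W1, p$se_W2, N, C)
    Zr <- se$out
    cache$se <- se$cache
  }

  if (!("ts_encoder" %in% ab)) {
    ts <- tse_fwd_batch(Zr, p, cfg$gate, N, C, mode, state)
    FGr <- ts$out
    state <- ts$state
    cache$tse <- ts$cache
    Fdim <- cfg$gate$F2
  } else {
    pw <- pool_fwd(Zr, cfg$gate$pool1 * cfg$gate$pool2)
    FGr <- pw$out
    cache$adapter <- pw$cache
    Fdim <- C
  }
  H <- rows_to_seq(FGr, N, Fdim)
  Tp <- dim(H)[2L]
  cache$Fdim <- Fdim; cache$Tp <- Tp

  if (!("hadte" %in% ab)) {
    if (!("residual_eca" %in% ab)) {
      ec <- eca_fwd_batch(H, p$eca_w)
      H <- ec$out
      cache$eca <- ec$cache
    }
    if (!("local_mha" %in% ab)) {
      mask <- build_local_mask(Tp, cfg$hadte$w, cfg$hadte$d)
      lm <- mha_fwd(H, p$loc_Wq, p$loc_Wk, p$loc_Wv, p$loc_Wo,
                    cfg$hadte$n_heads, cfg$hadte$head_dim, mask)
      cache$loc <- lm$cache
      H <- H + lm$out
    }
    if (!("global_mha" %in% ab)) {
      ln <- ln_fwd(H, p$ln_gamma, p$ln_beta)
      gm <- mha_fwd(ln$out, p$glob_Wq, p$glob_Wk, p$glob_Wv, p$glob_Wo,
                    cfg$hadte$n_heads, cfg$hadte$head_dim, NULL)
      cache$ln <- ln$cache; cache$glob <- gm$cache
      H <- H + gm$out
    }
    tc <- tcn_fwd_batch(H, p, cfg$hadte, mode)
    cache$tcn <- tc$cache
    H <- tc$out
  }
  feats <- matrix(H[, Tp, ], Fdim, N)
  logits <- crossprod(p$fc_W, feats) + p$fc_b
  cache$feats <- feats
  list(logits = logits, features = feats, cache = cache, state = state)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg; p <- model$params; ab <- cfg$ablation
  N <- cache$N; C <- cache$C; Fdim <- cache$Fdim; Tp <- cache$Tp
  g <- list(fc_W = cache$feats %*% t(dlogits), fc_b = rowSums(dlogits))
  dfeats <- p$fc_W %*% dlogits
  dH <- array(0, c(Fdim, Tp, N))
  dH[, Tp, ] <- dfeats

  if (!("hadte" %in% ab)) {
    tc <- tcn_bwd_batch(dH, p, cfg$hadte, cache$tcn)
    g <- c(g, tc$grads)
    dH <- tc$dX
    if (!("global_mha" %in% ab)) {
      gm <- mha_bwd(dH, p$glob_Wq, p$glob_Wk, p$glob_Wv, p$glob_Wo, cache$glob)
      ln <- ln_bwd(gm$dX, cache$ln)
      g$glob_Wq <- gm$dWq; g$glob_Wk <- gm$dWk
      g$glob_Wv <- gm$dWv; g$glob_Wo <- gm$dWo
      g$ln_gamma <- ln$dgamma; g$ln_beta <- ln$dbeta
      dH <- dH + ln$dX                  # residual + pre-LN branch
    }
    if (!("local_mha" %in% ab)) {
      lm <- mha_bwd(dH, p$loc_Wq, p$loc_Wk, p$loc_Wv, p$loc_Wo, cache$loc)
      g$loc_Wq <- lm$dWq; g$loc_Wk <- lm$dWk
      g$loc_Wv <- lm$dWv; g$loc_Wo <- lm$dWo
      dH <- dH + lm$dX
    }
    if (!("residual_eca" %in% ab)) {
      ec <- eca_bwd_batch(dH, p$eca_w, cache$eca)
      g$eca_w <- ec$dw
      dH <- ec$dX
    }
  }

  dFGr <- seq_to_rows(dH)
  if (!("ts_encoder" %in% ab)) {
    ts <- tse_bwd_batch(dFGr, p, cache$tse)
    g <- c(g, ts$grads)
    dZr <- ts$dX
  } else {
    dZr <- pool_bwd(dFGr, cache$adapter)
  }
  if (!("channel_attention" %in% ab)) {
    se <- se_bwd_batch(dZr, p$se_W1, p$se_W2, cache$se)
    g$se_W1 <- se$dW1; g$se_W2 <- se$dW2
    dZr <- se$dX
  }
  gc <- gc_bwd_batch(rows_to_zm(dZr, N), cache$gc)
  g$cheb_w <- gc$dw
  g
}

#' Class probabilities for a batch of trials
#'
#' Runs the model in deterministic evaluation mode and applies the softmax;
#' every row is a probability vector (nonnegative, summing to one).
#'
#' @param model A `gahtnet_model`.
#' @param X Array, batch x electrodes x samples (a [trial_set()] is also
#'   accepted).
#' @return Matrix, batch x classes.
#' @export
predict_proba <- function(model, X) {
  if (inherits(X, "trial_set")) X <- X$data
  fw <- model_forward(model, X, "eval")
  t(softmax_cols(fw$logits))
}

#' Predicted 0-based class labels
#' @inheritParams predict_proba
#' @return Integer vector of labels in `[0, n_classes)`.
#' @export
predict_labels <- function(model, X) {
  max.col(predict_proba(model, X)) - 1L
}

#' Pre-classifier embeddings
#'
#' The deep temporal feature vector handed to the classifier, one row per
#' trial; exportable for external visualisation (e.g. t-SNE).
#'
#' @inheritParams predict_proba
#' @return Matrix, batch x feature-dimension.
#' @export
model_embeddings <- function(model, X) {
  if (inherits(X, "trial_set")) X <- X$data
  t(model_forward(model, X, "eval")$features)
}

#' Mean cross-entropy loss
#'
#' `L = -(1/N) sum_n sum_m y_nm log(p_nm)`, with predicted probabilities
#' clipped at 1e-12 so a zero probability at the true class yields a large
#' finite loss.
#'
#' @param probs Matrix, batch x classes, rows summing to one.
#' @param labels Integer vector of 0-based labels, or a one-hot matrix.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (is.matrix(labels)) labels <- max.col(labels) - 1L
  if (length(labels) != nrow(probs))
    stop("labels length must match the number of rows")
  pt <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(pt, 1e-12)))
}

#' Train a GAH-TNet model
#'
#' Adam optimisation of the softmax cross-entropy with minibatches, a
#' stratified validation holdout, early stopping on validation accuracy,
#' and restoration of the best-epoch weights. A fixed seed makes the run
#' reproducible on a single device: it controls the holdout draw, the
#' shuffling, and the dropout masks.
#'
#' @param model A `gahtnet_model` from [build_model()].
#' @param train A [trial_set()] containing at least two classes.
#' @param tcfg A [train_config()].
#' @param verbose Print a line every `verbose` epochs (0 = silent).
#' @return List with the trained `model` and a `history` data frame
#'   (per-epoch train loss/accuracy, validation accuracy, plus the best and
#'   stopped epoch as attributes).
#' @export
train_model <- function(model, train, tcfg = train_config(), verbose = 0L) {
  y <- train$labels
  if (length(unique(y)) < 2L)
    stop("training set must contain at least two classes")
  set.seed(tcfg$seed)
  n <- length(y)
  val_idx <- unlist(lapply(unique(y), function(k) {
    ik <- which(y == k)
    sample(ik, max(1L, floor(length(ik) * tcfg$val_fraction)))
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- train$data[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- train$data[val_idx, , , drop = FALSE]; yva <- y[val_idx]

  opt <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, state = model$bn_state,
               epoch = 0L)
  since <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  stopped <- tcfg$max_epochs

  for (ep in seq_len(tcfg$max_epochs)) {
    ord <- sample(length(ytr))
    losses <- c(); correct <- 0L
    for (b0 in seq(1L, length(ord), by = tcfg$batch_size)) {
      bi <- ord[b0:min(b0 + tcfg$batch_size - 1L, length(ord))]
      Xb <- Xtr[bi, , , drop = FALSE]; yb <- ytr[bi]
      fw <- model_forward(model, Xb, "train")
      model$bn_state <- fw$state
      probs <- softmax_cols(fw$logits)                 # M x batch
      pt <- probs[cbind(yb + 1L, seq_along(yb))]
      losses <- c(losses, mean(-log(pmax(pt, 1e-12))))
      correct <- correct + sum(max.col(t(probs)) - 1L == yb)
      dlogits <- probs
      dlogits[cbind(yb + 1L, seq_along(yb))] <-
        dlogits[cbind(yb + 1L, seq_along(yb))] - 1
      dlogits <- dlogits / length(yb)
      grads <- model_backward(model, fw$cache, dlogits)
      st <- adam_step(model$params, grads, opt, lr = tcfg$lr)
      model$params <- st$params
      opt <- st$opt
    }
    val_acc <- mean(predict_labels(model, Xva) == yva)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   train_acc = correct / length(ytr),
                                   val_acc = val_acc))
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %d  loss %.4f  train %.3f  val %.3f",
                      ep, mean(losses), correct / length(ytr), val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params,
                   state = model$bn_state, epoch = ep)
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= tcfg$patience) { stopped <- ep; break }
    }
  }
  model$params <- best$params
  model$bn_state <- best$state
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "stopped_epoch") <- stopped
  list(model = model, history = hist)
}

#' Save / load a model checkpoint
#'
#' Single-file container of the named parameter arrays, the configuration,
#' the graph, and the batch-norm running statistics.
#'
#' @param model A `gahtnet_model`.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  structure(readRDS(path), class = "gahtnet_model")
}

#' Model-fitting closure for evaluation protocols
#'
#' Returns a `fit(train_ts)` function suitable for [run_protocol()]: it
#' builds a model matched to the data geometry, trains it, and returns a
#' predictor function.
#'
#' @param graph A [spatial_graph()].
#' @param gate,hadte Block configurations.
#' @param tcfg A [train_config()].
#' @param ablation Ablation flags applied to every fit.
#' @return A function `train_ts -> (test_ts -> labels)`.
#' @export
gahtnet_fitter <- function(graph, gate = gate_config(),
                           hadte = hadte_config(), tcfg = train_config(),
                           ablation = character(0)) {
  force(graph); force(gate); force(hadte); force(tcfg); force(ablation)
  function(train_ts) {
    cfg <- model_config(n_classes = train_ts$n_classes,
                        n_electrodes = dim(train_ts$data)[2L],
                        gate = gate, hadte = hadte,
                        input_samples = dim(train_ts$data)[3L],
                        ablation = ablation)
    model <- build_model(cfg, graph, seed = tcfg$seed)
    model <- train_model(model, train_ts, tcfg)$model
    function(test_ts) predict_labels(model, test_ts)
  }
}
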