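# Metrics (accuracy, Cohen's kappa), confusion matrices, the exact Wilcoxon
# signed-rank test, and orchestration of the subject-dependent and
# leave-one-subject-out protocols.

#' Confusion matrix from label vectors
#'
#' Entry (i, j) counts trials of true class i predicted as class j
#' (0-based labels; row/column 1 is class 0).
#'
#' @param true,pred Equal-length integer label vectors in `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return `n_classes` x `n_classes` count matrix.
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  if (length(true) != length(pred)) stop("label vectors differ in length")
  labs <- c(true, pred)
  if (any(labs < 0L | labs >= n_classes))
    stop(sprintf("labels must lie in [0, %d)", n_classes))
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true))
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  dimnames(cm) <- list(true = paste0("t", 0:(n_classes - 1L)),
                       pred = paste0("p", 0:(n_classes - 1L)))
  cm
}

#' Classification accuracy of a confusion matrix
#'
#' The proportion of correctly predicted trials: the trace over the total.
#' In the binary case this is (TP + TN) / (TP + TN + FP + FN).
#'
#' @param confusion Square count matrix.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(confusion))) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` the trace over the total and expected agreement
#' `p_e = sum_i row_i * col_i / total^2`. When `p_e = 1` (all mass in a
#' single cell) the statistic is defined as 0 with a warning.
#'
#' @param confusion Square count matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  cm <- as.matrix(confusion)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate confusion matrix (expected agreement 1); kappa set to 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Exact Wilcoxon signed-rank test for paired scores
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped
#' (Wilcoxon's original treatment) and ties receive average ranks. For
#' n <= 25 retained pairs the null distribution of the positive-rank sum is
#' computed exactly by enumerating sign assignments via the
#' generating-polynomial recursion (doubled ranks keep half-integer average
#' ranks exact); larger n uses the normal approximation with tie and
#' continuity corrections. Nine uniformly signed differences give
#' p = 2/512.
#'
#' @param scores_a,scores_b Equal-length paired score vectors.
#' @return List with `statistic` (positive-rank sum V), `p_value`
#'   (two-sided), `n` (pairs retained) and `method`.
#' @export
wilcoxon_signed_rank <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors differ in length")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero; no information")
  if (n < 5L)
    stop(sprintf("only %d nonzero difference(s); need at least 5", n))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))          # doubled ranks are integers
    tot <- sum(r2)
    cnt <- numeric(tot + 1L)                # counts over W2 = 0..tot
    cnt[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cnt[seq_len(tot + 1L - ri)])
      cnt <- cnt + shifted
    }
    w2 <- round(2 * V)
    p_le <- sum(cnt[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(cnt[(w2 + 1L):(tot + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}

#' Significance marker for a p-value
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise.
#'
#' @param p P-value.
#' @return Character marker.
#' @export
signif_marker <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Run an evaluation protocol
#'
#' Subject-dependent protocols split each subject's sessions into train and
#' test partitions ([subject_dependent_split()]); the LOSO protocol builds
#' one fold per held-out subject ([loso_folds()]). For every fold the
#' training partition is z-scored on itself, the test partition with the
#' training statistics, the supplied `fit` closure is trained, and
#' accuracy/kappa are recorded per subject together with the pooled
#' confusion matrix. The runner asserts that no trial identity appears in
#' both partitions of any fold.
#'
#' @param trials A [trial_set()] with subject/session metadata.
#' @param protocol `"dependent-2a"`, `"dependent-2b"`, or `"loso"`.
#' @param fit Function `train_ts -> (test_ts -> labels)`; see
#'   [gahtnet_fitter()] and [bandpower_oracle_classify()]-based closures.
#' @param normalize Z-score with training statistics (default TRUE).
#' @return An `eval_result`: per-subject table, means, pooled confusion.
#' @export
run_protocol <- function(trials, protocol = c("dependent-2a", "dependent-2b",
                                              "loso"),
                         fit, normalize = TRUE) {
  protocol <- match.arg(protocol)
  folds <- if (protocol == "loso") {
    loso_folds(trials)
  } else {
    lapply(unique(trials$subject), function(s) {
      sp <- subject_dependent_split(
        trials_subset(trials, which(trials$subject == s)),
        if (protocol == "dependent-2a") "2a" else "2b")
      list(train = sp$train, test = sp$test, subject = s)
    })
  }
  M <- trials$n_classes
  conf <- matrix(0L, M, M)
  rows <- NULL
  for (fd in folds) {
    if (length(intersect(paste(fd$train$subject, fd$train$session,
                               fd$train$trial_id),
                         paste(fd$test$subject, fd$test$session,
                               fd$test$trial_id))) > 0L)
      stop("protocol leakage: a trial appears in both partitions")
    tr <- fd$train; te <- fd$test
    if (normalize) {
      te <- zscore_channels(te, stats_from = tr)
      tr <- zscore_channels(tr)
    }
    predictor <- fit(tr)
    pred <- predictor(te)
    cm <- confusion_matrix(te$labels, pred, M)
    conf <- conf + cm
    rows <- rbind(rows, data.frame(subject = fd$subject,
                                   accuracy = accuracy(cm),
                                   kappa = cohen_kappa(cm)))
  }
  structure(list(per_subject = rows,
                 mean_accuracy = mean(rows$accuracy),
                 mean_kappa = mean(rows$kappa),
                 confusion = conf, protocol = protocol),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> protocol %s, %d subject(s)\n",
              x$protocol, nrow(x$per_subject)))
  df <- rbind(x$per_subject,
              data.frame(subject = "Mean", accuracy = x$mean_accuracy,
                         kappa = x$mean_kappa))
  df$accuracy <- sprintf("%.2f%%", 100 * df$accuracy)
  df$kappa <- sprintf("%.2f", as.numeric(df$kappa))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write evaluation results as CSV
#'
#' One row per subject plus a `Mean` row (subject, protocol, accuracy,
#' kappa); the pooled confusion matrix goes to a second file if a path is
#' given.
#'
#' @param res An `eval_result`.
#' @param path Output CSV path.
#' @param confusion_path Optional path for the confusion matrix CSV.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(res, path, confusion_path = NULL) {
  df <- rbind(res$per_subject,
              data.frame(subject = "Mean", accuracy = res$mean_accuracy,
                         kappa = res$mean_kappa))
  df <- cbind(df[, "subject", drop = FALSE], protocol = res$protocol,
              df[, c("accuracy", "kappa")])
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(confusion_path))
    utils::write.csv(as.data.frame(res$confusion), confusion_path,
                     row.names = TRUE)
  invisible(path)
}
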