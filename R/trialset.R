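#' Labeled epoched EEG trials
#'
#' The universal pipeline currency: a (trials x channels x time) array with
#' integer class labels and per-trial subject/session metadata. Labels are
#' 0-based (`0 .. n_classes-1`), sample indices are 0-based, and epoch
#' windows are half-open `[start, end)`.
#'
#' @param data Numeric array, trials x channels x time.
#' @param labels Integer class label per trial, each in `[0, n_classes)`.
#' @param fs Sampling rate in Hz.
#' @param subject Per-trial subject identifier (recycled if scalar).
#' @param session Per-trial session number (recycled if scalar).
#' @param class_names Optional class name per label value.
#' @param channel_names Optional electrode labels (length = channels).
#' @return A `trial_set` object.
#' @export
trial_set <- function(data, labels, fs, subject = 1L, session = 1L,
                      class_names = NULL, channel_names = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("data must be a 3-D trials x channels x time array")
  n <- dim(data)[1L]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("length(labels) must equal the number of trials")
  n_classes <- if (n > 0L) max(labels) + 1L else 0L
  if (!is.null(class_names)) n_classes <- max(n_classes, length(class_names))
  if (n > 0L && (any(labels < 0L) || any(labels >= n_classes)))
    stop("labels must lie in [0, n_classes)")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  subject <- rep_len(subject, n)
  session <- rep_len(as.integer(session), n)
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2L])
    stop("channel_names length must equal the channel count")
  structure(list(data = data, labels = labels, fs = fs,
                 subject = subject, session = session,
                 n_classes = n_classes,
                 class_names = class_names %||% paste0("class", seq_len(n_classes) - 1L),
                 channel_names = channel_names,
                 trial_id = if (n > 0L) seq_len(n) else integer(0)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz, %d classes\n",
              d[1L], d[2L], d[3L], x$fs, x$n_classes))
  cat(sprintf("  subjects: %s | sessions: %s\n",
              paste(unique(x$subject), collapse = ","),
              paste(unique(x$session), collapse = ",")))
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

n_trials <- function(ts) dim(ts$data)[1L]

#' Subset a trial set by trial index
#' @param ts A [trial_set()].
#' @param idx Trial indices to keep.
#' @return A `trial_set` with the selected trials (identities preserved).
#' @export
trials_subset <- function(ts, idx) {
  out <- ts
  out$data <- ts$data[idx, , , drop = FALSE]
  out$labels <- ts$labels[idx]
  out$subject <- ts$subject[idx]
  out$session <- ts$session[idx]
  out$trial_id <- ts$trial_id[idx]
  out
}

#' Concatenate trial sets along the trial axis
#' @param ... `trial_set` objects with matching channel/time geometry.
#' @return The combined `trial_set`; trial identities are kept unique.
#' @export
trials_bind <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !inherits(parts[[1L]], "trial_set"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  d0 <- dim(parts[[1L]]$data)[-1L]
  for (p in parts) {
    if (!identical(dim(p$data)[-1L], d0)) stop("channel/time geometry differs")
    if (p$fs != parts[[1L]]$fs) stop("sampling rates differ")
  }
  data <- do.call(abind3, lapply(parts, `[[`, "data"))
  out <- trial_set(data,
                   unlist(lapply(parts, `[[`, "labels")),
                   parts[[1L]]$fs,
                   unlist(lapply(parts, `[[`, "subject")),
                   unlist(lapply(parts, `[[`, "session")),
                   class_names = parts[[1L]]$class_names,
                   channel_names = parts[[1L]]$channel_names)
  offs <- cumsum(c(0L, vapply(parts, n_trials, integer(1L))))
  out$trial_id <- unlist(lapply(seq_along(parts), function(i)
    parts[[i]]$trial_id + offs[i] * 0L + (i - 1L) * 10000000L))
  out
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1L)))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[(at + 1L):(at + k), , ] <- a
    at <- at + k
  }
  out
}

#' Extract cue-locked epochs from a recording
#'
#' Cuts one trial per matching event, spanning the half-open window
#' `[cue - t_pre, cue + t_post)`; each trial holds exactly
#' `round(fs * (t_pre + t_post))` samples. At 250 Hz with `t_pre = 0.5` and
#' `t_post = 4` this is the canonical 1125-sample segment (4.5 s starting
#' 0.5 s before the cue). Epochs that would cross a recording boundary are
#' dropped with a warning.
#'
#' @param rec A `raw_recording` from [read_gdf()] or built in memory.
#' @param t_pre Seconds before the cue included in the epoch (>= 0).
#' @param t_post Seconds after the cue.
#' @param event_codes Integer event codes to epoch, in class order: the
#'   first code becomes label 0, the second label 1, and so on.
#' @param subject,session Metadata stamped on the trials.
#' @param class_names Optional class names (defaults to the event codes).
#' @return A [trial_set()].
#' @export
extract_epochs <- function(rec, t_pre, t_post, event_codes,
                           subject = 1L, session = 1L, class_names = NULL) {
  if (t_pre + t_post <= 0) stop("epoch window must have positive duration")
  ev <- rec$events
  keep <- ev$code %in% event_codes
  if (!any(keep)) stop("no events with the requested codes")
  ev <- ev[keep, , drop = FALSE]
  fs <- rec$fs
  n_samp <- as.integer(round(fs * (t_pre + t_post)))
  pre <- as.integer(round(fs * t_pre))
  start <- ev$sample - pre                     # 0-based first sample
  ok <- start >= 0L & (start + n_samp) <= ncol(rec$signal)
  if (any(!ok))
    warning(sprintf("dropped %d epoch(s) extending beyond the recording",
                    sum(!ok)))
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  if (nrow(ev) == 0L) stop("no epochs remain inside the recording bounds")
  C <- nrow(rec$signal)
  data <- array(0, c(nrow(ev), C, n_samp))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- rec$signal[, (start[i] + 1L):(start[i] + n_samp)]
  labels <- match(ev$code, event_codes) - 1L
  trial_set(data, labels, fs, subject = subject, session = session,
            class_names = class_names %||% paste0("code", event_codes),
            channel_names = rec$channel_names)
}

#' Z-score trials per channel using training-set statistics
#'
#' Standardises each channel to zero mean and unit variance:
#' `z = (x - mu) / sigma`, where `mu` and the population variance `sigma^2`
#' are computed per channel over every sample of `stats_from` (all trials
#' and time points pooled) and applied to `trials`. Passing the training
#' partition as `stats_from` for both partitions prevents test-set leakage:
#' the test data never contributes to the statistics.
#'
#' @param trials The [trial_set()] to normalise.
#' @param stats_from The trial set providing the statistics (defaults to
#'   `trials` itself).
#' @return The normalised `trial_set`.
#' @export
zscore_channels <- function(trials, stats_from = trials) {
  if (n_trials(stats_from) == 0L) stop("stats_from is empty")
  if (dim(trials$data)[2L] != dim(stats_from$data)[2L])
    stop("channel counts differ between the two trial sets")
  C <- dim(stats_from$data)[2L]
  mu <- numeric(C); sg <- numeric(C)
  for (c in seq_len(C)) {
    v <- as.vector(stats_from$data[, c, ])
    mu[c] <- mean(v)
    sg[c] <- sqrt(mean((v - mu[c])^2))   # population variance
  }
  if (any(sg == 0)) {
    ch <- which(sg == 0)
    nm <- if (!is.null(stats_from$channel_names))
      stats_from$channel_names[ch] else as.character(ch)
    stop(sprintf("zero variance on channel(s): %s", paste(nm, collapse = ", ")))
  }
  out <- trials
  for (c in seq_len(C))
    out$data[, c, ] <- (trials$data[, c, ] - mu[c]) / sg[c]
  attr(out, "zscore_stats") <- list(mean = mu, sd = sg)
  out
}

#' Session-based subject-dependent split
#'
#' Reproduces the within-subject evaluation splits: under the four-class
#' protocol (`"2a"`) session 1 trains and session 2 tests; under the
#' two-class protocol (`"2b"`) sessions 1-3 train and sessions 4-5 test.
#' Train and test are disjoint by construction (no trial appears in both).
#'
#' @param trials A [trial_set()] for one subject carrying session metadata.
#' @param protocol `"2a"` or `"2b"`.
#' @return List with elements `train` and `test`.
#' @export
subject_dependent_split <- function(trials, protocol = c("2a", "2b")) {
  protocol <- match.arg(protocol)
  need <- if (protocol == "2a") list(train = 1L, test = 2L)
          else list(train = 1:3, test = 4:5)
  have <- unique(trials$session)
  missing <- setdiff(c(need$train, need$test), have)
  if (length(missing) > 0L)
    stop(sprintf("protocol %s needs session(s) %s, absent from the data",
                 protocol, paste(missing, collapse = ", ")))
  list(train = trials_subset(trials, which(trials$session %in% need$train)),
       test = trials_subset(trials, which(trials$session %in% need$test)))
}

#' Leave-one-subject-out folds
#'
#' Builds one fold per subject: fold i tests subject i and trains on the
#' pooled trials of every other subject. The test sets partition the data:
#' pairwise disjoint and jointly exhaustive.
#'
#' @param trials A [trial_set()] with at least two distinct subjects.
#' @return A list of `list(train, test, subject)` folds.
#' @export
loso_folds <- function(trials) {
  subjects <- unique(trials$subject)
  if (length(subjects) < 2L) stop("LOSO requires at least two subjects")
  lapply(subjects, function(s) {
    list(train = trials_subset(trials, which(trials$subject != s)),
         test = trials_subset(trials, which(trials$subject == s)),
         subject = s)
  })
}

#' Cache a trial set on disk / reload it
#'
#' Single-file cache of the epoched array plus metadata (RDS container;
#' the schema mirrors the in-memory `trial_set`: `data`, `labels`, and the
#' `fs`/`subject`/`session` attributes).
#'
#' @param ts A [trial_set()].
#' @param path File path.
#' @return `path` (write) or the `trial_set` (read).
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  saveRDS(unclass(ts), path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("trial cache not found: %s", path))
  x <- readRDS(path)
  out <- trial_set(x$data, x$labels, x$fs, x$subject, x$session,
                   x$class_names, x$channel_names)
  out$trial_id <- x$trial_id
  out
}
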