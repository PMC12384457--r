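test_that("GDF round-trip preserves sampling rate, signal and events", {
  rec <- make_test_recording(fs = 250, dur_s = 10, channels = 2L,
                             cues = c(1.0, 5.0), codes = c(7L, 9L))
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(rec, path)
  back <- read_gdf(path)
  expect_equal(back$fs, 250)
  expect_equal(nrow(back$events), 2L)
  expect_equal(back$events$code, c(7L, 9L))
  expect_equal(back$events$sample, rec$events$sample)
  expect_equal(back$channel_names, rec$channel_names)
  # float32 storage: agreement to single precision
  expect_lt(max(abs(back$signal - rec$signal)), 1e-5)
})

test_that("unreadable GDF inputs raise structured errors", {
  expect_error(read_gdf("/nonexistent/file.gdf"), "not found.*file.gdf")
  bad <- withr::local_tempfile(fileext = ".gdf")
  writeBin(charToRaw("EDF+nonsense padding padding"), bad)
  expect_error(read_gdf(bad), "not a GDF file")
  rec <- make_test_recording(dur_s = 4)
  trunc <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(rec, trunc)
  full <- readBin(trunc, "raw", file.size(trunc))
  writeBin(full[1:(length(full) - 4000L)], trunc)
  expect_error(read_gdf(trunc), "truncated")
})

test_that("epoch extraction obeys the half-open window arithmetic", {
  rec <- make_test_recording(fs = 250, dur_s = 30)
  ts <- extract_epochs(rec, t_pre = 0.5, t_post = 4.0, event_codes = c(1L, 2L))
  expect_equal(dim(ts$data)[3L], 1125L)
  expect_equal(dim(ts$data)[1L], 4L)
  expect_equal(ts$labels, c(0L, 1L, 0L, 1L))
  # the first sample of an epoch is exactly cue - round(fs*t_pre)
  cue <- rec$events$sample[1L]
  expect_equal(ts$data[1L, 1L, 1L], rec$signal[1L, cue - 125L + 1L])
  # half-open: last sample is cue + round(fs*t_post) - 1
  expect_equal(ts$data[1L, 1L, 1125L], rec$signal[1L, cue + 1000L])

  rec100 <- make_test_recording(fs = 100, dur_s = 30)
  ts100 <- extract_epochs(rec100, 0, 1.0, c(1L, 2L))
  expect_equal(dim(ts100$data)[3L], 100L)
})

test_that("epoch length formula holds across sampling rates and windows", {
  set.seed(20)
  for (i in 1:10) {
    fs <- sample(c(100, 128, 250, 500), 1L)
    t_pre <- sample(c(0, 0.25, 0.5), 1L)
    t_post <- sample(c(1, 2, 3.5), 1L)
    rec <- make_test_recording(fs = fs, dur_s = 30, channels = 1L)
    ts <- extract_epochs(rec, t_pre, t_post, c(1L, 2L))
    expect_equal(dim(ts$data)[3L], round(fs * (t_pre + t_post)))
  }
})

test_that("boundary epochs are dropped with a warning, empty sets error", {
  rec <- make_test_recording(fs = 250, dur_s = 30)
  rec$events <- rbind(rec$events, data.frame(sample = 10L, code = 1L))
  expect_warning(ts <- extract_epochs(rec, 0.5, 4.0, c(1L, 2L)),
                 "dropped 1 epoch")
  expect_equal(dim(ts$data)[1L], 4L)
  expect_error(extract_epochs(rec, 0.5, 4.0, event_codes = 42L),
               "no events")
  early <- rec
  early$events <- data.frame(sample = 10L, code = 1L)
  expect_warning(expect_error(extract_epochs(early, 0.5, 4.0, 1L), "bounds"))
})

test_that("z-scoring uses population statistics and guards degeneracy", {
  x <- array(0, c(1L, 1L, 3L))
  x[1L, 1L, ] <- c(1, 2, 3)
  ts <- trial_set(x, 0L, fs = 10, class_names = "a")
  z <- zscore_channels(ts)
  expect_equal(as.vector(z$data[1L, 1L, ]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  z2 <- zscore_channels(z)
  expect_equal(z2$data, z$data, tolerance = 1e-6)

  const <- trial_set(array(5, c(2L, 2L, 4L)), c(0L, 1L), fs = 10,
                     channel_names = c("C3", "C4"))
  expect_error(zscore_channels(const), "C3")
})

test_that("training statistics transfer to the test partition without leakage", {
  set.seed(4)
  tr <- trial_set(array(rnorm(20 * 2 * 50, mean = 3, sd = 2),
                        c(20L, 2L, 50L)), rep(0:1, 10L), fs = 50)
  te <- trial_set(array(rnorm(10 * 2 * 50, mean = -5, sd = 7),
                        c(10L, 2L, 50L)), rep(0:1, 5L), fs = 50)
  zte <- zscore_channels(te, stats_from = tr)
  st <- attr(zte, "zscore_stats")
  # statistics come from the training set alone: perturbing the test set
  # leaves them unchanged
  te2 <- te; te2$data <- te2$data * 100
  expect_equal(attr(zscore_channels(te2, stats_from = tr), "zscore_stats"), st)
  # and the training set itself standardises to mean 0, variance 1
  ztr <- zscore_channels(tr)
  for (c in 1:2) {
    v <- as.vector(ztr$data[, c, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-4)
  }
})

test_that("session splits reproduce the evaluation protocols", {
  set.seed(8)
  mk <- function(sessions) {
    n <- 6L * length(sessions)
    trial_set(array(rnorm(n * 2 * 10), c(n, 2L, 10L)),
              rep_len(0:1, n), fs = 10,
              session = rep(sessions, each = 6L))
  }
  sp <- subject_dependent_split(mk(1:2), "2a")
  expect_equal(unique(sp$train$session), 1L)
  expect_equal(unique(sp$test$session), 2L)
  expect_equal(n_distinct <- length(intersect(sp$train$trial_id,
                                              sp$test$trial_id)), 0L)
  expect_equal(dim(sp$train$data)[1L] + dim(sp$test$data)[1L], 12L)

  sp_b <- subject_dependent_split(mk(1:5), "2b")
  expect_equal(sort(unique(sp_b$train$session)), 1:3)
  expect_equal(sort(unique(sp_b$test$session)), 4:5)

  expect_error(subject_dependent_split(mk(1L), "2a"), "session")
})

test_that("LOSO folds partition subjects exactly", {
  mk_multi <- function(S) {
    n <- 4L * S
    trial_set(array(rnorm(n * 2 * 10), c(n, 2L, 10L)), rep_len(0:1, n),
              fs = 10, subject = rep(seq_len(S), each = 4L))
  }
  folds <- loso_folds(mk_multi(9L))
  expect_length(folds, 9L)
  for (fd in folds) {
    expect_equal(length(unique(fd$train$subject)), 8L)
    expect_false(fd$subject %in% fd$train$subject)
  }
  test_subjects <- unlist(lapply(folds, function(f) unique(f$test$subject)))
  expect_setequal(test_subjects, 1:9)
  expect_equal(anyDuplicated(test_subjects), 0L)
  # totals preserved in every fold
  expect_true(all(vapply(folds, function(f)
    dim(f$train$data)[1L] + dim(f$test$data)[1L], numeric(1L)) == 36L))

  f2 <- loso_folds(mk_multi(2L))
  expect_length(f2, 2L)
  expect_equal(f2[[1L]]$train$subject, f2[[2L]]$test$subject)
  expect_error(loso_folds(mk_multi(1L)), "two subjects")
})

test_that("trial caches round-trip", {
  ts <- tiny_trials(n_per_class = 3L)
  path <- withr::local_tempfile(fileext = ".rds")
  write_trials(ts, path)
  back <- read_trials(path)
  expect_equal(back$data, ts$data)
  expect_equal(back$labels, ts$labels)
  expect_equal(back$fs, ts$fs)
})
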