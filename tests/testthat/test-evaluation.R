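test_that("confusion matrices count true-by-predicted pairs", {
  expect_equal(unname(confusion_matrix(c(0L, 1L), c(0L, 1L), 2L)), diag(c(1L, 1L)))
  cm <- confusion_matrix(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L), 2L)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2L))
  expect_equal(unname(rowSums(cm)), c(2L, 2L))   # conservation per true class
  expect_error(confusion_matrix(c(0L, 2L), c(0L, 1L), 2L), "labels")
  expect_error(confusion_matrix(0L, c(0L, 1L), 2L), "length")
})

test_that("accuracy reproduces hand arithmetic and Monte-Carlo chance", {
  expect_equal(accuracy(diag(c(3L, 7L))), 1.0)
  # TP=3, FN=2, FP=1, TN=2 -> (3+2)/8
  cm <- matrix(c(3L, 1L, 2L, 2L), 2L)
  expect_equal(accuracy(cm), 0.625)
  expect_error(accuracy(matrix(0L, 2L, 2L)), "empty")

  set.seed(77)
  true <- sample(0:3, 10000L, replace = TRUE)
  pred <- sample(0:3, 10000L, replace = TRUE)
  expect_lt(abs(accuracy(confusion_matrix(true, pred, 4L)) - 0.25), 0.02)
})

test_that("Cohen's kappa matches hand arithmetic and edge conventions", {
  expect_equal(cohen_kappa(diag(c(5L, 5L))), 1.0)
  one_col <- matrix(c(6L, 6L, 0L, 0L), 2L)   # everything predicted class 0
  expect_equal(cohen_kappa(one_col), 0.0)
  cm <- matrix(c(30L, 9L, 6L, 27L), 2L)      # p_o = 57/72, p_e = 1/2
  expect_equal(cohen_kappa(cm), 0.5833, tolerance = 1e-4)
  expect_warning(k <- cohen_kappa(matrix(c(5L, 0L, 0L, 0L), 2L)), "degenerate")
  expect_equal(k, 0)
  # agreement with recomputation from raw labels
  set.seed(21)
  true <- sample(0:2, 60L, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, true, sample(0:2, 60L, replace = TRUE))
  cm2 <- confusion_matrix(true, pred, 3L)
  po <- mean(true == pred)
  pe <- sum(table(factor(true, 0:2)) * table(factor(pred, 0:2))) / 60^2
  expect_equal(cohen_kappa(cm2), (po - pe) / (1 - pe))
})

test_that("exact Wilcoxon signed-rank matches enumeration and wilcox.test", {
  # nine uniformly positive differences: p = 2 / 2^9
  res <- wilcoxon_signed_rank(1:9 + 10, rep(10, 9L))
  expect_equal(res$p_value, 2 / 512)
  expect_equal(res$statistic, 45)
  expect_equal(res$method, "exact")

  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 2)), "at least 5")
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")

  set.seed(9)
  a <- rnorm(9); b <- rnorm(9)
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(b, a)
  expect_equal(r1$p_value, r2$p_value)           # symmetry under swap
  expect_equal(r1$statistic + r2$statistic, 45)  # rank sums complement

  # tie-free cases: agreement with the reference exact implementation
  for (i in 1:10) {
    n <- sample(6:12, 1L)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$statistic, unname(ref$statistic))
  }

  # brute-force enumeration oracle including ties, n <= 12
  brute_p <- function(d) {
    d <- d[d != 0]; n <- length(d); r <- rank(abs(d))
    v <- sum(r[d > 0])
    ws <- vapply(0:(2^n - 1), function(m) {
      sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0])
    }, numeric(1L))
    min(1, 2 * min(mean(ws <= v + 1e-9), mean(ws >= v - 1e-9)))
  }
  set.seed(10)
  for (i in 1:5) {
    d <- sample(c(-3:-1, 1:4), 8L, replace = TRUE)  # heavy ties
    expect_equal(wilcoxon_signed_rank(d, rep(0, 8L))$p_value, brute_p(d),
                 tolerance = 1e-12)
  }
})

test_that("significance markers follow the two-star convention", {
  expect_equal(signif_marker(0.2), "")
  expect_equal(signif_marker(0.03), "*")
  expect_equal(signif_marker(0.004), "**")
})

test_that("LOSO protocol yields one fold per subject with exact aggregation", {
  mont <- montage_2b()
  cfg <- synth_config(n_subjects = 9L, trials_per_class = 6L, n_classes = 2L,
                      montage = mont, snr_db = 12,
                      erd_map = default_erd_map(mont, 2L, attenuation = 0.8),
                      seed = 19L)
  ts <- generate_trials(cfg)
  res <- run_protocol(ts, "loso", centroid_fitter(cfg$erd_map))
  expect_s3_class(res, "eval_result")
  expect_equal(nrow(res$per_subject), 9L)
  expect_equal(res$mean_accuracy, mean(res$per_subject$accuracy),
               tolerance = 1e-12)
  expect_equal(res$mean_kappa, mean(res$per_subject$kappa), tolerance = 1e-12)
  expect_equal(sum(res$confusion), dim(ts)[1L])

  csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_csv(res, csv)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$subject[10L], "Mean")
})

test_that("subject-dependent protocol separates sessions and beats chance", {
  mont <- montage_2b()
  cfg <- synth_config(n_subjects = 2L, trials_per_class = 8L, n_classes = 2L,
                      montage = mont, snr_db = 12, n_sessions = 2L,
                      erd_map = default_erd_map(mont, 2L, attenuation = 0.8),
                      seed = 29L)
  ts <- generate_trials(cfg)
  res <- run_protocol(ts, "dependent-2a", centroid_fitter(cfg$erd_map))
  expect_equal(nrow(res$per_subject), 2L)
  # high-SNR strong-ERD data: well above the 0.5 chance floor
  expect_gte(res$mean_accuracy, 0.5 + 0.3)
  expect_error(run_protocol(ts, "bogus", centroid_fitter(cfg$erd_map)))
})
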