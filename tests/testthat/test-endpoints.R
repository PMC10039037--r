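test_that("confusion metrics match the stated definitions", {
  t <- sw(c("sleep", "sleep", "wake", "wake", "sleep"))
  cm <- confusion(t, t)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 100)
  expect_equal(cm$precision, 100)
  expect_equal(cm$accuracy, 100)
  expect_equal(cm$f1, 100)

  # TP=3 FN=1 TN=2 FP=2
  truth <- sw(c(rep("sleep", 4), rep("wake", 4)))
  pred <- sw(c("sleep", "sleep", "sleep", "wake", "sleep", "sleep", "wake", "wake"))
  cm <- confusion(pred, truth)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(3, 1, 2, 2))
  expect_equal(cm$sensitivity, 75)
  expect_equal(cm$specificity, 50)
  expect_equal(cm$precision, 60)
  expect_equal(cm$f1, 200 / 3, tolerance = 1e-12)

  expect_error(confusion(sw(rep("sleep", 3)), sw(rep("sleep", 4))),
               class = "actisleep_alignment_error")
})

test_that("zero-denominator metrics are flagged undefined, not zero", {
  cm <- confusion(sw(rep("wake", 5)), sw(rep("wake", 5)))
  expect_true(is.na(cm$sensitivity))   # no truth sleep
  expect_true(is.na(cm$precision))     # no predicted sleep
  expect_equal(cm$specificity, 100)
  expect_true(is.na(cm$f1))            # perfect all-wake agreement
  cm <- confusion(sw(rep("wake", 5)), sw(c(rep("sleep", 3), "wake", "wake")))
  expect_equal(cm$f1, 0)               # no TP but disagreement exists
})

test_that("F1 equals the harmonic-mean closed form on random inputs", {
  withr::local_seed(41)
  for (i in 1:50) {
    n <- sample(2:300, 1)
    cm <- confusion(sw(rand_labels(n)), sw(rand_labels(n)))
    if (!is.na(cm$precision) && !is.na(cm$sensitivity) && cm$tp > 0) {
      expect_equal(cm$f1, 2 * cm$precision * cm$sensitivity /
                            (cm$precision + cm$sensitivity), tolerance = 1e-12)
    }
  }
})

test_that("endpoints follow the onset/offset definitions", {
  s <- sw(rep("sleep", 10))
  e <- endpoints(s)
  expect_equal(e$waso_min, 0)
  expect_equal(e$tst_min, 5)
  expect_equal(e$se_pct, 100)

  e <- endpoints(sw(c("wake", "sleep", "sleep", "wake", "sleep", "wake")))
  expect_equal(e$onset_epoch, 2L)
  expect_equal(e$offset_epoch, 5L)
  expect_equal(e$waso_min, 0.5)
  expect_equal(e$tst_min, 1.5)
  expect_equal(e$se_pct, 50)

  e <- endpoints(sw(rep("wake", 6)))
  expect_true(is.na(e$waso_min))
  expect_equal(e$tst_min, 0)
  expect_equal(e$se_pct, 0)

  # k-consecutive onset rule shifts onset past isolated sleep epochs
  e <- endpoints(sw(c("sleep", "wake", "sleep", "sleep", "sleep", "wake")),
                 onset_rule = list(consecutive_epochs = 3L))
  expect_equal(e$onset_epoch, 3L)
})

test_that("cohort aggregation averages per-subject statistics", {
  t1 <- sw(rand_labels(50)); cm1 <- confusion(sw(rand_labels(50)), t1)
  expect_equal(cohort_aggregate(list(cm1))$mean[["accuracy"]], cm1$accuracy)
  expect_equal(cohort_aggregate(list(cm1))$sd[["accuracy"]], 0)

  mk <- function(sens) structure(list(accuracy = 80, sensitivity = sens,
                                      specificity = 50, precision = 70, f1 = 75),
                                 class = "confusion_stats")
  agg <- cohort_aggregate(list(mk(70), mk(80)))
  expect_equal(agg$mean[["sensitivity"]], 75)

  # independent mean/SD oracle over random subjects
  withr::local_seed(43)
  stats_list <- lapply(1:10, function(i) confusion(sw(rand_labels(100)),
                                                   sw(rand_labels(100))))
  agg <- cohort_aggregate(stats_list)
  vals <- vapply(stats_list, function(s) s$sensitivity, numeric(1))
  expect_equal(agg$mean[["sensitivity"]], mean(vals, na.rm = TRUE))
  expect_equal(agg$sd[["sensitivity"]], sd(vals), tolerance = 1e-12)
  expect_error(cohort_aggregate(list()), class = "actisleep_parameter_error")
})

test_that("Bland-Altman statistics match closed forms", {
  b <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(b$me, 0); expect_equal(b$rmse, 0); expect_equal(b$ci_width, 0)

  b <- bland_altman(c(20, 0), c(10, 10))   # differences +10, -10
  expect_equal(b$me, 0)
  expect_equal(b$rmse, 10)

  b <- bland_altman(c(13, 15, 17), c(10, 10, 10))   # differences 3,5,7
  expect_equal(b$me, 5)
  expect_equal(b$rmse, sqrt(83 / 3), tolerance = 1e-12)
  expect_equal(b$loa_lower, 5 - 1.96 * 2)
  expect_equal(b$loa_upper, 5 + 1.96 * 2)
  expect_equal(b$ci_width, b$loa_upper - b$loa_lower)

  expect_true(is.na(bland_altman(5, 3)$loa_upper))     # n < 2
  expect_true(is.na(bland_altman(c(1, 2), c(1, 1))$pearson_r))  # zero variance
})

test_that("Bland-Altman is antisymmetric in ME and swap-invariant in spread", {
  withr::local_seed(47)
  for (i in 1:20) {
    a <- rnorm(10, 50, 20); b <- rnorm(10, 40, 15)
    f <- bland_altman(a, b); g <- bland_altman(b, a)
    expect_equal(f$me, -g$me, tolerance = 1e-12)
    expect_equal(f$rmse, g$rmse, tolerance = 1e-12)
    expect_equal(f$ci_width, g$ci_width, tolerance = 1e-12)
    expect_equal(f$pearson_r, g$pearson_r, tolerance = 1e-12)
  }
})

test_that("selection retains exactly the algorithms meeting both thresholds", {
  mk <- function(name, sens, spec) {
    s <- cohort_aggregate(list(structure(list(accuracy = 75, sensitivity = sens,
                                              specificity = spec, precision = 76,
                                              f1 = 78), class = "confusion_stats")),
                          algorithm = name)
    s
  }
  res <- select_algorithms(list(mk("posture", 83.6, 47.5),
                                mk("window_thr", 86.2, 42)))
  expect_length(res, 1L)
  expect_equal(res[[1]]$algorithm, "posture")
  expect_true(res[[1]]$selected)
  expect_length(select_algorithms(list()), 0L)
})
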