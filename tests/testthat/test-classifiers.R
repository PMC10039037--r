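presets <- load_presets()

test_that("preset file is versioned, validated, and overridable", {
  expect_true(presets$version >= 1)
  p2 <- load_presets(overrides = list(oakley = list(threshold = 20)))
  expect_equal(p2$oakley$threshold, 20)
  expect_equal(p2$oakley$weights[["0"]], 1)   # untouched fields survive
  expect_error(load_presets(overrides = list(sazonov = list(probability_threshold = 2))),
               class = "actisleep_format_error")
})

test_that("weighted-window model scores and thresholds counts", {
  ck <- linear_window_model(presets$cole_kripke, "cole_kripke")
  # zero input: score 0 < 1 -> all sleep
  expect_true(all(is_sleep(classify_linear_window(rep(0, 10), ck))))
  # one 1-min epoch of 10000 counts: score 0.001*230*10000 = 2300 -> wake
  cnt <- rep(0, 20); cnt[11:12] <- 5000
  s <- classify_linear_window(cnt, ck)
  expect_identical(s$labels[11:12], c("wake", "wake"))
  # single-epoch input stays defined via zero padding
  expect_length(classify_linear_window(7, ck)$labels, 1L)
  expect_error(classify_linear_window(numeric(0), ck),
               class = "actisleep_parameter_error")
})

test_that("degenerate single-weight model reduces to plain thresholding", {
  m <- linear_window_model(list(weights = list("0" = 1), scale = 1,
                                threshold = 42, sleep_when = "score_below",
                                epoch_basis_s = 30), "thr")
  withr::local_seed(21)
  for (i in 1:10) {
    x <- round(runif(sample(1:50, 1), 0, 100))
    expect_identical(is_sleep(classify_linear_window(x, m)), x < 42)
  }
})

test_that("Sadeh statistics reproduce hand-computed cases", {
  p <- presets$sadeh
  # all zeros: PS = intercept = 7.601 >= 0 -> sleep
  expect_true(all(is_sleep(classify_sadeh(rep(0, 20), p))))
  # constant 75 counts/min in the NAT band [50,100): interior epochs have
  # MW5 = 75, NAT = 11, SD6 = 0, LG = ln 76 -> PS ~ -12.2 -> wake
  s <- classify_sadeh(rep(37.5, 40), p)
  expect_true(all(!is_sleep(s)))
  ps_interior <- p$intercept + p$w_mean * 75 + p$w_nat * 11 + p$w_log * log(76)
  expect_lt(ps_interior, p$sleep_threshold)
  expect_length(classify_sadeh(rep(0, 7), p)$labels, 7L)
})

test_that("Sazonov logistic model follows its preset coefficients", {
  p <- presets$sazonov
  expect_true(all(is_sleep(classify_sazonov(rep(0, 10), p))))
  expect_equal(stats::plogis(p$intercept), 0.849, tolerance = 1e-3)
  expect_true(all(!is_sleep(classify_sazonov(rep(1e5, 10), p))))
  expect_length(classify_sazonov(rep(0, 3), p)$labels, 3L)
})

test_that("z-angle matches closed-form orientations", {
  p <- presets$vanhees
  expect_equal(compute_z_angle(const_recording(0, 0, 1, n = 400), p)[1], 90)
  expect_equal(compute_z_angle(const_recording(1, 0, 0, n = 400), p)[1], 0)
  expect_equal(compute_z_angle(const_recording(0.5, 0.5, sqrt(2) / 2, n = 400), p)[1],
               45, tolerance = 1e-9)
  expect_warning(compute_z_angle(const_recording(0, 0, 0, n = 400), p),
                 "undefined orientation")
})

test_that("z-angle is invariant to positive rescaling of the input", {
  withr::local_seed(13)
  n <- 2000
  r1 <- raw_recording("a", 0, 40, rnorm(n), rnorm(n), 1 + rnorm(n))
  r2 <- raw_recording("a", 0, 40, 3.7 * r1$ax, 3.7 * r1$ay, 3.7 * r1$az)
  expect_equal(compute_z_angle(r1, presets$vanhees),
               compute_z_angle(r2, presets$vanhees), tolerance = 1e-12)
})

test_that("sustained-stillness runs become sleep, movement wake", {
  p <- presets$vanhees
  mkang <- function(v) structure(v, block_s = 5)
  # constant orientation all night -> all sleep
  g <- grid30(20)
  s <- classify_vanhees(mkang(rep(30, 120)), p, g)
  expect_true(all(is_sleep(s)))
  # 90-degree flip every 2 min -> no still run reaches 5 min -> all wake
  flips <- rep(rep(c(0, 90), each = 24), length.out = 240)
  s <- classify_vanhees(mkang(flips), p, grid30(40))
  expect_true(all(!is_sleep(s)))
  # 10 min static then continuous large movement
  ang <- c(rep(10, 120), 10 + cumsum(rep(8, 120)) %% 120)
  s <- classify_vanhees(mkang(ang), p, grid30(40))
  expect_true(all(is_sleep(s)[1:20]))
  expect_true(all(!is_sleep(s)[22:40]))
})

test_that("reference classifiers emit constant labels", {
  expect_identical(reference_classifier(grid30(4), "all_sleep")$labels,
                   rep("sleep", 4))
  expect_identical(reference_classifier(grid30(1), "all_wake")$labels, "wake")
  truth <- sw(c("sleep", "sleep", "wake", "sleep"))
  cm <- confusion(reference_classifier(grid30(4), "all_sleep"), truth)
  expect_equal(cm$sensitivity, 100)
  expect_equal(cm$specificity, 0)
})

test_that("every classifier returns one label per epoch at awkward lengths", {
  ck <- linear_window_model(presets$cole_kripke, "ck")
  for (n in c(1:5, 11, 23)) {
    x <- rep(0, n)
    expect_length(classify_linear_window(x, ck)$labels, n)
    expect_length(classify_sadeh(x, presets$sadeh)$labels, n)
    expect_length(classify_sazonov(x, presets$sazonov)$labels, n)
  }
})
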