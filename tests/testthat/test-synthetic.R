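test_that("hypnogram generation is deterministic and respects limits", {
  cfg <- synth_config(night_duration_min = 120, seed = 9)
  g1 <- gen_hypnogram(cfg, 1)
  g2 <- gen_hypnogram(cfg, 1)
  expect_identical(g1$hypnogram$stages, g2$hypnogram$stages)
  expect_equal(g1$hypnogram$grid$n_epochs, 240L)
  expect_true(g1$hypnogram$stages[1] == "W")   # nights start in wake

  # degenerate limit: infinite wake bout mean -> all-wake night
  allw <- gen_hypnogram(synth_config(night_duration_min = 60,
                                     wake_bout_mean_min = Inf, seed = 2), 1)
  expect_true(all(allw$hypnogram$stages == "W"))
  expect_error(gen_hypnogram(synth_config(night_duration_min = 0.1), 1),
               class = "actisleep_parameter_error")
})

test_that("empirical mean sleep-bout length tracks the configured mean", {
  cfg <- synth_config(night_duration_min = 5000, sleep_bout_mean_min = 50,
                      wake_bout_mean_min = 5, seed = 101)
  st <- gen_hypnogram(cfg, 1)$hypnogram$stages
  r <- rle(st != "W")
  sleep_lens <- r$lengths[r$values]
  # interior bouts only (edge bouts are truncated by the night)
  sleep_lens <- sleep_lens[-c(1, length(sleep_lens))]
  expect_equal(mean(sleep_lens) / 2, 50, tolerance = 0.05)
})

test_that("stored analytic endpoints equal endpoints() on the hypnogram", {
  for (sd in 1:5) {
    cfg <- synth_config(night_duration_min = 240, seed = sd)
    gt <- gen_hypnogram(cfg, sd)
    e <- endpoints(binarize_hypnogram(gt$hypnogram))
    expect_identical(e$waso_min, gt$endpoints$waso_min)
    expect_identical(e$tst_min, gt$endpoints$tst_min)
    expect_identical(e$se_pct, gt$endpoints$se_pct)
    expect_identical(e$onset_epoch, gt$endpoints$onset_epoch)
    expect_identical(e$offset_epoch, gt$endpoints$offset_epoch)
  }
})

test_that("binarization of generated nights exercises every stage label", {
  cfg <- synth_config(night_duration_min = 480, seed = 3)
  st <- gen_hypnogram(cfg, 1)$hypnogram$stages
  expect_setequal(unique(st), c("W", "N1", "N2", "N3", "REM"))
})

test_that("acceleration matches the night's length and purity contract", {
  cfg <- synth_config(night_duration_min = 10, sleep_residual_movement_prob = 0,
                      sensor_noise_sd_g = 0, seed = 4)
  gt <- gen_hypnogram(cfg, 1)
  r <- gen_accel(gt, cfg)
  expect_equal(length(r$ax), round(10 * 60 * 85.7))
  expect_equal(r$sample_rate_hz, 85.7)
  # noiseless sleep epochs are exactly constant
  slp_ep <- which(gt$hypnogram$stages != "W")
  if (length(slp_ep)) {
    spe <- round(85.7 * 30)
    e <- slp_ep[1]
    seg <- r$ax[((e - 1) * spe + 1):(e * spe)]
    expect_equal(diff(range(seg)), 0)
  }
})

test_that("a noiseless pure-sleep night yields all-zero counts end to end", {
  cfg <- synth_config(night_duration_min = 10, wake_bout_mean_min = 0.4,
                      sleep_bout_mean_min = 1e7, sleep_residual_movement_prob = 0,
                      sensor_noise_sd_g = 0, seed = 6)
  gt <- gen_hypnogram(cfg, 1)
  stopifnot(mean(gt$hypnogram$stages != "W") > 0.9)
  r <- gen_accel(gt, cfg)
  cc <- compute_counts(downsample_mean(r))
  slp <- gt$hypnogram$stages[seq_len(cc$grid$n_epochs)] != "W"
  expect_true(all(cc$cx[slp] == 0))
  expect_true(all(cc$cy[slp] == 0))
  expect_true(all(cc$cz[slp] == 0))
})

test_that("cohorts are reproducible and subjects differ", {
  cfg <- synth_config(n_subjects = 3, night_duration_min = 30, seed = 12)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_length(c1, 3L)
  expect_identical(c1[[2]]$recording$ax, c2[[2]]$recording$ax)
  expect_false(identical(c1[[1]]$truth$hypnogram$stages,
                         c1[[2]]$truth$hypnogram$stages) &&
               identical(c1[[1]]$recording$ax, c1[[2]]$recording$ax))
})

test_that("fixture cohorts land on disk in the documented formats", {
  d <- withr::local_tempdir()
  write_fixture_cohort(d, synth_config(n_subjects = 2, night_duration_min = 10,
                                       seed = 8))
  files <- list.files(d)
  expect_setequal(files, c("S01_accel.csv", "S01_hypnogram.csv",
                           "S02_accel.csv", "S02_hypnogram.csv"))
  r <- read_accel_csv(file.path(d, "S01_accel.csv"))
  expect_equal(r$sample_rate_hz, 85.7, tolerance = 1e-3)
  h <- read_hypnogram_csv(file.path(d, "S01_hypnogram.csv"))
  expect_equal(h$grid$n_epochs, 20L)
})
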