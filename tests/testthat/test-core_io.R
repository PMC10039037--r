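test_that("raw_recording enforces its invariants", {
  expect_s3_class(raw_recording("a", 0, 85.7, 0:2 / 10, 0:2 / 10, rep(1, 3)),
                  "raw_recording")
  expect_error(raw_recording("a", 0, 85.7, 1:3, 1:2, 1:3), class = "actisleep_format_error")
  expect_error(raw_recording("a", 0, -1, 1, 1, 1), class = "actisleep_parameter_error")
  expect_error(raw_recording("a", 0, 10, c(1, NA), c(1, 1), c(1, 1)),
               class = "actisleep_data_error")
})

test_that("epoch_grid rejects lengths not dividing 60 s", {
  expect_silent(epoch_grid(0, 5, 15L))
  expect_error(epoch_grid(0, 5, 45L), class = "actisleep_parameter_error")
  expect_error(epoch_grid(0, -1), class = "actisleep_parameter_error")
})

test_that("acceleration CSV reader parses, infers rate, and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z",
               "0.00,0,0,1", "0.01,0,0,1", "0.02,0,0,1"), f)
  r <- read_accel_csv(f)
  expect_equal(r$sample_rate_hz, 100)
  expect_length(r$ax, 3L)
  expect_equal(r$az, rep(1, 3))

  writeLines(c("timestamp,x,y,z", "0.02,0,0,1", "0.01,0,0,1", "0.00,0,0,1"), f)
  expect_error(read_accel_csv(f), class = "actisleep_data_error")

  writeLines(c("timestamp,x,y,z", "0.00,0,0,1", "0.01,0,0,1", "0.02,0,0,1",
               "0.03,0,0,1", "0.08,0,0,1"), f)
  expect_error(read_accel_csv(f), class = "actisleep_gap_error")

  writeLines(c("time,x,y,z", "0,0,0,1"), f)
  expect_error(read_accel_csv(f), class = "actisleep_format_error")
})

test_that("write/read round trips are value-identical", {
  withr::local_seed(11)
  n <- 857
  r <- raw_recording("rt", 1700000000, 85.7,
                     rnorm(n), rnorm(n), 1 + rnorm(n))
  f <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(r, f)
  r2 <- read_accel_csv(f, subject_id = "rt")
  expect_equal(r2$sample_rate_hz, r$sample_rate_hz, tolerance = 1e-6)
  expect_equal(r2$ax, r$ax, tolerance = 1e-6)
  expect_equal(r2$ay, r$ay, tolerance = 1e-6)
  expect_equal(r2$az, r$az, tolerance = 1e-6)
  expect_equal(as.numeric(r2$start_time), as.numeric(r$start_time), tolerance = 1e-5)

  h <- hypnogram(grid30(7), c("W", "N1", "N2", "N3", "N2", "REM", "W"))
  write_hypnogram_csv(h, f)
  h2 <- read_hypnogram_csv(f)
  expect_identical(h2$stages, h$stages)
  expect_equal(h2$grid$n_epochs, 7L)

  s <- sw(rand_labels(20), source = "algo")
  write_sleepwake_csv(s, f)
  s2 <- read_sleepwake_csv(f)
  expect_identical(s2$labels, s$labels)
  expect_identical(s2$source, "algo")
})

test_that("hypnogram reader rejects unknown stage labels with location", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,stage", "0,W", "30,S5"), f)
  expect_error(read_hypnogram_csv(f), "S5.*row 2", class = "actisleep_format_error")
})

test_that("binarize_hypnogram maps W to wake and all sleep stages to sleep", {
  b <- binarize_hypnogram(hypnogram(grid30(3), c("W", "N2", "REM")))
  expect_identical(b$labels, c("wake", "sleep", "sleep"))
  expect_identical(b$source, "PSG")

  allw <- binarize_hypnogram(hypnogram(grid30(4), rep("W", 4)))
  expect_true(all(allw$labels == "wake"))

  # elementwise oracle on a mixed input
  withr::local_seed(4)
  st <- sample(c("W", "N1", "N2", "N3", "REM"), 10, replace = TRUE)
  b <- binarize_hypnogram(hypnogram(grid30(10), st))
  oracle <- vapply(st, function(s) if (s == "W") "wake" else "sleep", "")
  expect_identical(b$labels, unname(oracle))
})

test_that("downsample_mean averages half-open windows and drops the partial tail", {
  r <- const_recording(0, 0, 1, n = round(85.7), fs = 85.7)   # 1 s of data
  d <- downsample_mean(r)
  expect_equal(d$sample_rate_hz, 40)
  expect_length(d$ax, 40L)
  expect_true(all(d$az == 1))

  # alternating +-1 at 80 Hz: brute-force window means; at 80 Hz sample i
  # (0-based) falls in 25-ms window i %/% 2 exactly
  n <- 160
  x <- rep(c(1, -1), n / 2)
  set.seed(6); x <- x + round(rnorm(n), 2)   # break the symmetry too
  r <- raw_recording("alt", 0, 80, x, rep(0, n), rep(0, n))
  d <- downsample_mean(r)
  win <- (seq_len(n) - 1L) %/% 2L + 1L
  oracle <- vapply(seq_len(n %/% 2L), function(w) mean(x[win == w]), numeric(1))
  expect_equal(d$ax, oracle)

  expect_error(downsample_mean(const_recording(fs = 30)),
               class = "actisleep_parameter_error")
  # identity at target rate
  r40 <- const_recording(n = 400, fs = 40)
  expect_identical(downsample_mean(r40), r40)
})

test_that("align_to_grid drops non-overlapping epochs and preserves pairing", {
  s <- sw(rand_labels(10))
  expect_identical(align_to_grid(s, s$grid)$labels, s$labels)

  # prediction starting one epoch early
  g <- grid30(9, start = 30)
  a <- align_to_grid(s, g)
  expect_identical(a$labels, s$labels[-1])
  expect_equal(as.numeric(a$grid$start_time), 30)

  # random offsets: brute-force timestamp intersection
  withr::local_seed(9)
  for (i in 1:20) {
    off1 <- sample(-5:5, 1); n1 <- sample(3:15, 1)
    off2 <- sample(-5:5, 1); n2 <- sample(3:15, 1)
    s1 <- sw(rand_labels(n1), start = off1 * 30)
    g2 <- grid30(n2, start = off2 * 30)
    t1 <- off1 * 30 + (seq_len(n1) - 1) * 30
    t2 <- off2 * 30 + (seq_len(n2) - 1) * 30
    shared <- intersect(t1, t2)
    if (!length(shared)) {
      expect_error(align_to_grid(s1, g2), class = "actisleep_alignment_error")
    } else {
      a <- align_to_grid(s1, g2)
      expect_identical(a$labels, s1$labels[t1 %in% shared])
      expect_equal(a$grid$n_epochs, length(shared))
    }
  }
})
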