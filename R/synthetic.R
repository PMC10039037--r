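# Synthetic cohort generator.
#
# Emulates the statistical structure the evaluation relies on: nights of
# 30-s PSG-aligned epochs alternating between wake and sleep bouts with
# geometric (memoryless) bout lengths; wake epochs carry sustained
# band-limited (0.5-3 Hz) wrist movement and periodic posture changes,
# sleep epochs are static gravity plus sensor noise, with an optional
# per-epoch chance of a residual movement burst emulating disturbed
# sleepers.  All randomness flows from a single master seed; per-subject
# streams are derived deterministically.

# evaluate expr under a local RNG seed without touching global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

derive_seed <- function(master, subject_index, stream) {
  (as.numeric(master) * 48271 + subject_index * 69621 + stream * 16807) %% 2147483563
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe an 8-h single-night laboratory cohort of 28 subjects
#' with fragmented, disorder-heavy sleep: 50-min mean sleep bouts broken by
#' 5-min mean wake bouts, moderate wrist movement (0.5 g) with a posture
#' shift every 2 min of wake, a 5% per-epoch chance of a 10-s residual
#' movement burst during sleep, 0.01 g sensor noise, and the 85.7 Hz
#' tri-axial sampling of the wrist device.
#'
#' @param n_subjects number of subjects; default 28.
#' @param night_duration_min night length in minutes; default 480.
#' @param epoch_length_s epoch length; default 30.
#' @param sleep_bout_mean_min,wake_bout_mean_min geometric mean bout
#'   lengths in minutes; `Inf` wake mean yields an all-wake night.
#' @param sleep_bout_min_min minimum sleep bout length in minutes (shifted
#'   geometric, mean preserved); default 5, the posture heuristic's minimum
#'   still duration, so that generated truth is separable by construction.
#' @param wake_movement_amplitude_g movement oscillation amplitude in g.
#' @param sleep_residual_movement_prob per-sleep-epoch probability of a
#'   movement burst.
#' @param residual_burst_s burst duration in seconds; default 10.
#' @param posture_shift_period_min wake posture-change period in minutes.
#' @param sensor_noise_sd_g Gaussian sensor noise SD in g.
#' @param sample_rate_hz sampling rate; default 85.7.
#' @param seed master seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 28L, night_duration_min = 480,
                         epoch_length_s = 30L,
                         sleep_bout_mean_min = 50, wake_bout_mean_min = 5,
                         sleep_bout_min_min = 5,
                         wake_movement_amplitude_g = 0.5,
                         sleep_residual_movement_prob = 0.05,
                         residual_burst_s = 10,
                         posture_shift_period_min = 2,
                         sensor_noise_sd_g = 0.01,
                         sample_rate_hz = 85.7, seed = 1L) {
  stopifnot(n_subjects >= 1L, night_duration_min > 0,
            sleep_bout_mean_min > 0, wake_bout_mean_min > 0,
            sleep_bout_min_min > 0,
            wake_movement_amplitude_g > 0,
            sleep_residual_movement_prob >= 0, sleep_residual_movement_prob <= 1,
            residual_burst_s > 0, posture_shift_period_min > 0,
            sensor_noise_sd_g >= 0, sample_rate_hz > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 night_duration_min = night_duration_min,
                 epoch_length_s = as.integer(epoch_length_s),
                 sleep_bout_mean_min = sleep_bout_mean_min,
                 sleep_bout_min_min = sleep_bout_min_min,
                 wake_bout_mean_min = wake_bout_mean_min,
                 wake_movement_amplitude_g = wake_movement_amplitude_g,
                 sleep_residual_movement_prob = sleep_residual_movement_prob,
                 residual_burst_s = residual_burst_s,
                 posture_shift_period_min = posture_shift_period_min,
                 sensor_noise_sd_g = sensor_noise_sd_g,
                 sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

SLEEP_STAGE_CYCLE <- c("N1", "N2", "N3", "N2", "REM")

#' Generate a ground-truth hypnogram for one subject
#'
#' A two-state alternating bout sequence starting in wake, with geometric
#' bout lengths at the configured means.  Sleep bouts are emitted as
#' N1/N2/N3/N2/REM in a fixed repeating cycle so binarization exercises
#' all stage labels.  Deterministic given `(seed, subject_index)`.
#'
#' @param cfg a [synth_config()].
#' @param subject_index 1-based subject number.
#' @return a `ground_truth` list with fields `hypnogram`
#'   ([hypnogram()]), `endpoints` ([endpoints()] computed analytically from
#'   the stage sequence) and `subject_index`.
#' @export
gen_hypnogram <- function(cfg, subject_index = 1L) {
  n_ep <- as.integer(round(cfg$night_duration_min * 60 / cfg$epoch_length_s))
  if (n_ep < 1L) stopf("actisleep_parameter_error", "zero-duration night")
  epm <- 60 / cfg$epoch_length_s
  mean_ep <- function(m) m * epm
  stages <- with_local_seed(derive_seed(cfg$seed, subject_index, 1L), {
    out <- character(0L)
    state_wake <- TRUE
    cycle_pos <- 0L
    while (length(out) < n_ep) {
      m <- if (state_wake) mean_ep(cfg$wake_bout_mean_min) else mean_ep(cfg$sleep_bout_mean_min)
      # sleep bouts have a floor at the configured minimum (shifted
      # geometric, mean preserved); scored sleep fragments shorter than
      # the posture heuristic's minimum still duration are not emulated
      floor_ep <- if (state_wake) 1 else
        min(mean_ep(cfg$sleep_bout_min_min), m)
      len <- if (!is.finite(m)) n_ep - length(out)
             else if (m <= floor_ep) as.integer(ceiling(floor_ep))
             else floor_ep + stats::rgeom(1L, 1 / (m - floor_ep + 1))
      len <- min(len, n_ep - length(out))
      if (state_wake) {
        out <- c(out, rep("W", len))
      } else {
        idx <- (cycle_pos + seq_len(len) - 1L) %% length(SLEEP_STAGE_CYCLE) + 1L
        out <- c(out, SLEEP_STAGE_CYCLE[idx])
        cycle_pos <- cycle_pos + len
      }
      state_wake <- !state_wake
    }
    out
  })
  grid <- epoch_grid(0, n_ep, cfg$epoch_length_s)
  h <- hypnogram(grid, stages)
  # analytic endpoints straight from the stage sequence
  slp <- stages != "W"
  epmin <- cfg$epoch_length_s / 60
  if (any(slp)) {
    onset <- which(slp)[1L]; offset <- max(which(slp))
    ep <- structure(list(waso_min = sum(!slp[onset:offset]) * epmin,
                         tst_min = sum(slp) * epmin,
                         se_pct = 100 * sum(slp) / n_ep,
                         onset_epoch = onset, offset_epoch = offset),
                    class = "sleep_endpoints")
  } else {
    ep <- structure(list(waso_min = NA_real_, tst_min = 0, se_pct = 0,
                         onset_epoch = NA_integer_, offset_epoch = NA_integer_),
                    class = "sleep_endpoints")
  }
  structure(list(hypnogram = h, endpoints = ep, subject_index = subject_index),
            class = "ground_truth")
}

rand_unit_vec <- function() {
  v <- stats::rnorm(3L)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

# band-limited oscillation: three sinusoids with random frequencies in
# 0.5-3 Hz (inside the count passband), random phases and directions,
# total amplitude `amp`
movement_burst <- function(n, fs, amp) {
  f <- stats::runif(3L, 0.5, 3)
  ph <- stats::runif(3L, 0, 2 * pi)
  share <- c(0.5, 0.3, 0.2) * amp
  tt <- (seq_len(n) - 1L) / fs
  out <- matrix(0, n, 3L)
  for (k in 1:3) {
    dir <- rand_unit_vec()
    out <- out + outer(share[k] * sin(2 * pi * f[k] * tt + ph[k]), dir)
  }
  out
}

# gravity direction from azimuth and elevation (radians)
orient_vec <- function(az, el) {
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

#' Generate raw acceleration matching a ground-truth hypnogram
#'
#' Sleep epochs: constant gravity orientation plus Gaussian sensor noise,
#' with a movement burst inserted with the configured residual
#' probability.  Wake epochs: band-limited oscillation at the configured
#' amplitude, a discrete posture change every posture-shift period, and a
#' continuous slow elevation wander (15-25 degrees at ~0.1 Hz) so that the
#' forearm orientation, not only its high-frequency acceleration, varies
#' throughout wake as it does in real waking wear.
#' Deterministic given the config seed and the subject index.
#'
#' @param t a `ground_truth` from [gen_hypnogram()].
#' @param cfg a [synth_config()].
#' @return a [raw_recording()] at `cfg$sample_rate_hz`.
#' @export
gen_accel <- function(t, cfg) {
  h <- t$hypnogram
  n_ep <- h$grid$n_epochs
  fs <- cfg$sample_rate_hz
  spe <- as.integer(round(fs * cfg$epoch_length_s))
  slp <- h$stages != "W"
  shift_every <- max(1L, as.integer(round(cfg$posture_shift_period_min * 60 / cfg$epoch_length_s)))
  with_local_seed(derive_seed(cfg$seed, t$subject_index, 2L), {
    acc <- matrix(0, n_ep * spe, 3L)
    orient <- rand_unit_vec()
    az <- stats::runif(1L, 0, 2 * pi)
    el0 <- stats::runif(1L, -pi / 3, pi / 3)   # wrist-realistic elevation
    tt_ep <- (seq_len(spe) - 1L) / fs
    wake_run <- 0L
    for (e in seq_len(n_ep)) {
      rows <- ((e - 1L) * spe + 1L):(e * spe)
      if (slp[e]) {
        wake_run <- 0L
        seg <- matrix(orient, spe, 3L, byrow = TRUE)
        if (cfg$sleep_residual_movement_prob > 0 &&
            stats::runif(1L) < cfg$sleep_residual_movement_prob) {
          nb <- min(spe, as.integer(round(cfg$residual_burst_s * fs)))
          at <- sample.int(spe - nb + 1L, 1L)
          seg[at:(at + nb - 1L), ] <- seg[at:(at + nb - 1L), ] +
            movement_burst(nb, fs, cfg$wake_movement_amplitude_g)
        }
      } else {
        if (wake_run %% shift_every == 0L) {
          az <- stats::runif(1L, 0, 2 * pi)
          el0 <- stats::runif(1L, -pi / 3, pi / 3)
        }
        wake_run <- wake_run + 1L
        # slow elevation wander: orientation keeps changing between the
        # discrete posture shifts, as a moving forearm's does
        a_w <- stats::runif(1L, 15, 25) * pi / 180
        f_w <- stats::runif(1L, 0.08, 0.12)
        ph_w <- stats::runif(1L, 0, 2 * pi)
        el <- el0 + a_w * sin(2 * pi * f_w * tt_ep + ph_w)
        seg <- orient_vec(az, el) +
          movement_burst(spe, fs, cfg$wake_movement_amplitude_g)
        orient <- orient_vec(az, el[spe])[1L, ]   # sleep inherits last posture
      }
      acc[rows, ] <- seg
    }
    if (cfg$sensor_noise_sd_g > 0)
      acc <- acc + stats::rnorm(length(acc), sd = cfg$sensor_noise_sd_g)
    raw_recording(sprintf("S%02d", t$subject_index), h$grid$start_time, fs,
                  acc[, 1L], acc[, 2L], acc[, 3L])
  })
}

#' Generate a full synthetic cohort
#'
#' @param cfg a [synth_config()].
#' @return list of `n_subjects` elements, each
#'   `list(recording = raw_recording, truth = ground_truth)`; reproducible
#'   from the master seed.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lapply(seq_len(cfg$n_subjects), function(i) {
    gt <- gen_hypnogram(cfg, i)
    list(recording = gen_accel(gt, cfg), truth = gt)
  })
}

#' Materialize a small synthetic cohort as CSV files
#'
#' Writes per-subject acceleration and hypnogram files in the formats the
#' readers consume; used for fast end-to-end fixtures.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config()]; default 3 subjects x 2 h.
#' @return the directory path, invisibly.
#' @export
write_fixture_cohort <- function(dir, cfg = synth_config(n_subjects = 3L,
                                                       night_duration_min = 120)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in gen_cohort(cfg)) {
    id <- sub$recording$subject_id
    write_accel_csv(sub$recording, file.path(dir, sprintf("%s_accel.csv", id)))
    write_hypnogram_csv(sub$truth$hypnogram,
                        file.path(dir, sprintf("%s_hypnogram.csv", id)))
  }
  invisible(dir)
}
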