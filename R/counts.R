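# Activity-count derivation.
#
# Counts emulate the legacy actigraph data-reduction chain: the 40 Hz input
# is resampled to the band-pass filter's native 30 Hz, filtered to the
# 0.29-1.63 Hz movement band, scaled to the legacy ADC range, rectified,
# clipped at the saturation ceiling, dead-banded, quantized to 8-bit
# resolution, decimated to 10 Hz and accumulated per epoch.  Filtering is
# applied per epoch with steady-state initialization at the epoch's first
# sample, so each epoch's counts are a pure function of that epoch's
# samples: constant (gravity-only) input yields exactly zero, counts are
# invariant to adding a constant offset, and permuting input epochs
# permutes count epochs identically.

COUNT_FILTER_RATE_HZ <- 30
COUNT_BAND_HZ <- c(0.29, 1.63)
COUNT_ADC_GAIN <- (3 / 4096) / (2.6 / 256) * 237.5   # ~17.1274 per g
COUNT_CLIP <- 2.13          # saturation ceiling, scaled units
COUNT_DEADBAND <- 0.068     # values below are zeroed, scaled units
COUNT_RESOLUTION <- 2.13 / 128   # 8-bit quantization step
COUNT_ACCUM_RATE_HZ <- 10
COUNT_EPOCH_MAX <- 32767L        # 16-bit epoch counter saturation

count_filter_coefs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bf <- signal::butter(3, COUNT_BAND_HZ / (COUNT_FILTER_RATE_HZ / 2),
                           type = "pass")
      cache <<- list(b = bf$b, a = bf$a)
    }
    cache
  }
})

# band-pass with steady-state init for a constant at x[1]: previous inputs
# x[1], previous outputs 0 (the band-pass has zero DC gain), so constant
# input maps to exactly zero output.
bpf_apply <- function(x) {
  co <- count_filter_coefs()
  nb <- length(co$b)
  x1 <- stats::filter(c(rep(x[1L], nb - 1L), x), co$b, sides = 1)
  x1 <- x1[nb:length(x1)]
  as.numeric(stats::filter(x1, -co$a[-1L], method = "recursive",
                           init = rep(0, length(co$a) - 1L)))
}

count_one_epoch <- function(x, fs) {
  n30 <- COUNT_FILTER_RATE_HZ * 30L
  if (abs(fs - COUNT_FILTER_RATE_HZ) > 1e-9) {
    tin <- (seq_along(x) - 1L) / fs
    tout <- (seq_len(n30) - 1L) / COUNT_FILTER_RATE_HZ
    x <- stats::approx(tin, x, xout = tout, rule = 2)$y
  }
  y <- abs(bpf_apply(x) * COUNT_ADC_GAIN)
  y <- pmin(y, COUNT_CLIP)
  y[y < COUNT_DEADBAND] <- 0
  lev <- floor(y / COUNT_RESOLUTION)
  dec <- lev[seq(1L, length(lev), by = COUNT_FILTER_RATE_HZ / COUNT_ACCUM_RATE_HZ)]
  min(as.integer(sum(dec)), COUNT_EPOCH_MAX)
}

#' Per-axis activity counts on a count series grid
#'
#' @param grid an [epoch_grid()].
#' @param cx,cy,cz nonnegative integer vectors, one count per epoch per axis.
#' @return An object of class `count_series`.
#' @export
count_series <- function(grid, cx, cy, cz) {
  stopifnot(inherits(grid, "epoch_grid"))
  for (v in list(cx, cy, cz)) {
    if (length(v) != grid$n_epochs)
      stopf("actisleep_format_error", "count vectors must match grid length %d",
            grid$n_epochs)
    if (any(v < 0) || any(v != as.integer(v)))
      stopf("actisleep_data_error", "counts must be nonnegative integers")
  }
  structure(list(grid = grid, cx = as.integer(cx), cy = as.integer(cy),
                 cz = as.integer(cz)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d epochs; per-axis means %.1f / %.1f / %.1f\n",
              x$grid$n_epochs, mean(x$cx), mean(x$cy), mean(x$cz)))
  invisible(x)
}

#' Compute per-axis activity counts in 30-s epochs
#'
#' Input must already be at the 40 Hz rate produced by [downsample_mean()]
#' (30 Hz input is also accepted and skips the internal resampling step).
#' A trailing partial epoch is dropped.  Per-axis epoch counts saturate at
#' the 16-bit counter ceiling of 32767, emulating the fixed-width epoch
#' counters of legacy devices; beyond the corresponding input amplitude
#' counts are exactly constant.
#'
#' @param r a [raw_recording()] at 40 Hz (tolerance +-0.5 Hz) or 30 Hz.
#' @param epoch_length_s epoch length; must be 30.
#' @return a [count_series()] on the epoch grid anchored at the recording start.
#' @export
compute_counts <- function(r, epoch_length_s = 30L) {
  stopifnot(inherits(r, "raw_recording"))
  if (epoch_length_s != 30L)
    stopf("actisleep_parameter_error", "counts are defined on 30-s epochs")
  fs <- r$sample_rate_hz
  if (abs(fs - 40) > 0.5 && abs(fs - COUNT_FILTER_RATE_HZ) > 1e-6)
    stopf("actisleep_parameter_error",
          "compute_counts expects 40 Hz input (got %.4g Hz); run downsample_mean first",
          fs)
  spe <- round(fs * epoch_length_s)
  n_ep <- floor(n_samples(r) / spe)
  if (n_ep < 1L)
    stopf("actisleep_parameter_error", "recording shorter than one epoch")
  per_axis <- function(v) {
    vapply(seq_len(n_ep), function(e) {
      count_one_epoch(v[((e - 1L) * spe + 1L):(e * spe)], fs)
    }, integer(1L))
  }
  grid <- epoch_grid(r$start_time, n_ep, epoch_length_s)
  count_series(grid, per_axis(r$ax), per_axis(r$ay), per_axis(r$az))
}

#' Combine per-axis counts into the scalar series classifiers consume
#'
#' @param cs a [count_series()].
#' @param mode one of `"single_axis"`, `"vector_magnitude"` (default for the
#'   legacy classifiers), `"sixth_root_sum_squares"`.
#' @param axis which axis when `mode = "single_axis"`: `"x"`, `"y"` or `"z"`.
#' @return numeric vector of one nonnegative value per epoch.
#' @export
combine_axes <- function(cs, mode = c("vector_magnitude", "single_axis",
                                     "sixth_root_sum_squares"),
                         axis = c("x", "y", "z")) {
  stopifnot(inherits(cs, "count_series"))
  mode <- match.arg(mode)
  ss <- as.numeric(cs$cx)^2 + as.numeric(cs$cy)^2 + as.numeric(cs$cz)^2
  switch(mode,
         single_axis = {
           axis <- match.arg(axis)
           as.numeric(switch(axis, x = cs$cx, y = cs$cy, z = cs$cz))
         },
         vector_magnitude = sqrt(ss),
         sixth_root_sum_squares = ss^(1 / 6))
}

#' Write a count series (and optional combined series) to delimited text
#' @param cs a [count_series()].
#' @param path output file.
#' @param combined optional numeric vector (e.g. from [combine_axes()]).
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(cs, path, combined = NULL) {
  d <- data.frame(timestamp = sprintf("%.6f", grid_times(cs$grid)),
                  cx = cs$cx, cy = cs$cy, cz = cs$cz)
  if (!is.null(combined)) d$combined <- combined
  data.table::fwrite(d, path)
  invisible(path)
}
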