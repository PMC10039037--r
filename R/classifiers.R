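# Sleep-wake classifiers.
#
# All count-based classifiers consume a scalar per-epoch count series on
# the 30-s grid.  Models trained on a 1-min basis (Cole-Kripke, Oakley,
# Sadeh) aggregate 30-s counts by pairwise summation, classify on the
# 1-min basis and broadcast each decision back to its constituent 30-s
# epochs.  Window positions falling outside the recording read as zero
# counts.

# pairwise-sum 30-s counts to 1-min epochs; a trailing unpaired epoch forms
# its own (half) minute so output length maps back exactly.
aggregate_to_minutes <- function(counts) {
  n <- length(counts)
  grp <- (seq_len(n) - 1L) %/% 2L + 1L
  as.numeric(rowsum(as.numeric(counts), grp, reorder = TRUE))
}

broadcast_to_halves <- function(x, n30) {
  rep(x, each = 2L)[seq_len(n30)]
}

# windowed value lookup with zero padding outside the series
shifted <- function(x, off) {
  n <- length(x)
  if (off == 0L) return(x)
  if (off > 0L) c(x[-seq_len(min(off, n))], rep(0, min(off, n)))
  else c(rep(0, min(-off, n)), x[seq_len(max(n + off, 0L))])
}

check_counts_input <- function(counts, grid) {
  if (!length(counts))
    stopf("actisleep_parameter_error", "empty count series")
  if (!is.null(grid)) {
    if (grid$epoch_length_s != 30L)
      stopf("actisleep_parameter_error", "classifiers require a 30-s epoch grid")
    if (grid$n_epochs != length(counts))
      stopf("actisleep_alignment_error", "counts length %d != grid epochs %d",
            length(counts), grid$n_epochs)
  }
}

#' Classify sleep-wake with a weighted-window linear model
#'
#' Implements the Cole-Kripke / Oakley family: the epoch score is
#' `scale * sum_k weight(k) * counts(epoch + k)` over the model's epoch
#' offsets, with out-of-range epochs reading as zero; the epoch is scored
#' sleep when the score is below (or at-or-below) the threshold.
#'
#' @param counts numeric per-30-s-epoch count series (e.g. [combine_axes()]).
#' @param m a [linear_window_model()].
#' @param grid optional [epoch_grid()] for the output series; defaults to a
#'   grid starting at time 0.
#' @return a [sleepwake()] with `source = m$name`.
#' @export
classify_linear_window <- function(counts, m, grid = NULL) {
  stopifnot(inherits(m, "linear_window_model"))
  check_counts_input(counts, grid)
  n30 <- length(counts)
  x <- if (m$epoch_basis_s == 60L) aggregate_to_minutes(counts) else as.numeric(counts)
  score <- numeric(length(x))
  for (i in seq_along(m$offsets))
    score <- score + m$weights[i] * shifted(x, m$offsets[i])
  score <- m$scale * score
  slp <- if (m$sleep_when == "score_below") score < m$threshold else score <= m$threshold
  if (m$epoch_basis_s == 60L) slp <- broadcast_to_halves(slp, n30)
  if (is.null(grid)) grid <- epoch_grid(0, n30)
  sleepwake_from_logical(grid, slp, m$name)
}

#' Classify sleep-wake with the Sadeh activity-statistic model
#'
#' The per-minute sleep score is
#' `PS = intercept + w_mean*MW5 + w_nat*NAT + w_sd*SD6 + w_log*LG` where
#' MW5 is the mean count in the centered 11-min window, NAT the number of
#' window epochs with counts in the `[nat_low, nat_high)` band, SD6 the
#' standard deviation of the current and five preceding minutes, and
#' `LG = ln(counts + 1)`.  An epoch is sleep when `PS >= sleep_threshold`.
#' 30-s input is aggregated to minutes and decisions broadcast back.
#'
#' @param counts numeric per-30-s-epoch count series.
#' @param p Sadeh preset (see [load_presets()]); fields `intercept`,
#'   `w_mean`, `w_nat`, `w_sd`, `w_log`, `nat_low`, `nat_high`,
#'   `window_epochs_each_side`, `sd_window_epochs`, `sleep_threshold`.
#' @param grid optional output [epoch_grid()].
#' @return a [sleepwake()] with source `"sadeh"`.
#' @export
classify_sadeh <- function(counts, p, grid = NULL) {
  check_counts_input(counts, grid)
  n30 <- length(counts)
  x <- aggregate_to_minutes(counts)
  n <- length(x)
  k <- p$window_epochs_each_side
  win <- vapply(-k:k, function(o) shifted(x, o), numeric(n))
  if (n == 1L) win <- matrix(win, nrow = 1L)
  mw5 <- rowMeans(win)
  nat <- rowSums(win >= p$nat_low & win < p$nat_high)
  sdw <- vapply(-(p$sd_window_epochs - 1L):0L, function(o) shifted(x, o), numeric(n))
  if (n == 1L) sdw <- matrix(sdw, nrow = 1L)
  sd6 <- apply(sdw, 1L, stats::sd)
  lg <- log(x + 1)
  ps <- p$intercept + p$w_mean * mw5 + p$w_nat * nat + p$w_sd * sd6 + p$w_log * lg
  slp <- broadcast_to_halves(ps >= p$sleep_threshold, n30)
  if (is.null(grid)) grid <- epoch_grid(0, n30)
  sleepwake_from_logical(grid, slp, "sadeh")
}

#' Classify sleep-wake with the Sazonov logistic trailing-maximum model
#'
#' The score is `intercept + sum_w weight(w) * max(counts over the trailing
#' window of length w epochs)`; an epoch is sleep when
#' `logistic(score) >= probability_threshold`.
#'
#' @param counts numeric per-epoch count series (30-s basis).
#' @param p Sazonov preset with `intercept`, `window_weights` (named by
#'   trailing-window length), `probability_threshold`.
#' @param grid optional output [epoch_grid()].
#' @return a [sleepwake()] with source `"sazonov"`.
#' @export
classify_sazonov <- function(counts, p, grid = NULL) {
  check_counts_input(counts, grid)
  x <- as.numeric(counts)
  n <- length(x)
  wl <- as.integer(names(unlist(p$window_weights)))
  ww <- as.numeric(unlist(p$window_weights))
  score <- rep(p$intercept, n)
  trail_max <- x
  for (w in seq_len(max(wl))) {
    if (w > 1L) trail_max <- pmax(trail_max, shifted(x, -(w - 1L)))
    j <- match(w, wl)
    if (!is.na(j)) score <- score + ww[j] * trail_max
  }
  slp <- stats::plogis(score) >= p$probability_threshold
  if (is.null(grid)) grid <- epoch_grid(0, n)
  sleepwake_from_logical(grid, slp, "sazonov")
}

#' Compute the z-angle series from raw acceleration
#'
#' The posture angle of the forearm relative to horizontal:
#' `atan(az / sqrt(ax^2 + ay^2)) * 180 / pi`, computed on per-axis rolling
#' medians over `median_window_s`, then averaged over consecutive
#' `angle_block_s` blocks.  Values lie in `[-90, 90]` degrees.  Blocks with
#' an all-zero acceleration vector have undefined orientation and propagate
#' an angle of 0 with a warning.
#'
#' @param r a [raw_recording()] (g-scale, any rate).
#' @param p van Hees preset (see [load_presets()]).
#' @return numeric vector of per-block angles in degrees, with attributes
#'   `block_s` and `start_time`.
#' @export
compute_z_angle <- function(r, p = load_presets()$vanhees) {
  stopifnot(inherits(r, "raw_recording"))
  fs <- r$sample_rate_hz
  k <- max(1L, round(p$median_window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  rmed <- function(v) if (k >= length(v)) rep(stats::median(v), length(v))
                      else stats::runmed(v, k, endrule = "median")
  mx <- rmed(r$ax); my <- rmed(r$ay); mz <- rmed(r$az)
  denom <- sqrt(mx^2 + my^2)
  ang <- atan2(mz, denom) * 180 / pi
  zero <- denom == 0 & mz == 0
  if (any(zero)) {
    warning("all-zero acceleration vector: undefined orientation set to 0 degrees")
    ang[zero] <- 0
  }
  # assign samples to blocks by timestamp so block boundaries stay exact
  # even when the block length is not a whole number of samples
  tt <- (seq_along(ang) - 1L) / fs
  idx <- floor(tt / p$angle_block_s + 1e-9) + 1L
  nb <- floor(length(ang) / fs / p$angle_block_s + 1e-9)
  if (nb < 1L)
    stopf("actisleep_parameter_error", "recording shorter than one angle block")
  keep <- idx <= nb
  blk <- as.numeric(rowsum(ang[keep], idx[keep], reorder = TRUE)) /
    tabulate(idx[keep], nbins = nb)
  structure(blk, block_s = p$angle_block_s, start_time = r$start_time)
}

#' Classify sleep-wake from sustained z-angle invariance
#'
#' Successive absolute angle changes between blocks are computed; maximal
#' runs in which every change is below `angle_change_threshold_deg` and
#' whose spanned duration is at least `min_still_duration_min` are labelled
#' sleep, everything else wake.  Block labels are resampled to the 30-s
#' epoch grid by majority within each epoch, ties scoring wake.
#'
#' @param angles per-block angle series from [compute_z_angle()].
#' @param p van Hees preset.
#' @param grid target [epoch_grid()].
#' @return a [sleepwake()] with source `"vanhees"`.
#' @export
classify_vanhees <- function(angles, p, grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  bs <- attr(angles, "block_s")
  if (is.null(bs)) bs <- p$angle_block_s
  nb <- length(angles)
  still <- rep(FALSE, nb)
  if (nb >= 2L) {
    small <- abs(diff(angles)) < p$angle_change_threshold_deg
    r <- rle(small)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    need_blocks <- p$min_still_duration_min * 60 / bs
    for (i in seq_along(r$lengths)) {
      if (r$values[i] && (r$lengths[i] + 1L) >= need_blocks) {
        still[starts[i]:(ends[i] + 1L)] <- TRUE   # diffs j span blocks j-1..j
      }
    }
  } else if (nb == 1L) {
    still <- FALSE   # a single block cannot satisfy the minimum duration
  }
  bpe <- grid$epoch_length_s / bs
  if (bpe < 1 || abs(bpe - round(bpe)) > 1e-9)
    stopf("actisleep_alignment_error", "angle block length must divide the epoch length")
  bpe <- as.integer(round(bpe))
  slp <- logical(grid$n_epochs)
  for (e in seq_len(grid$n_epochs)) {
    idx <- ((e - 1L) * bpe + 1L):(e * bpe)
    idx <- idx[idx <= nb]
    if (!length(idx))
      stopf("actisleep_alignment_error", "angle blocks do not cover epoch %d", e)
    slp[e] <- sum(still[idx]) > length(idx) / 2   # tie -> wake
  }
  sleepwake_from_logical(grid, slp, "vanhees")
}

#' Constant reference classifiers
#'
#' The all-sleep / all-wake baselines: on any truth containing both classes
#' the all-sleep classifier scores sensitivity 100% and specificity 0%, and
#' the all-wake classifier specificity 100% and F1 0.
#'
#' @param grid an [epoch_grid()] with at least one epoch.
#' @param mode `"all_sleep"` or `"all_wake"`.
#' @return a [sleepwake()].
#' @export
reference_classifier <- function(grid, mode = c("all_sleep", "all_wake")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "epoch_grid"), grid$n_epochs >= 1L)
  sleepwake(grid, rep(if (mode == "all_sleep") "sleep" else "wake",
                      grid$n_epochs), mode)
}
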