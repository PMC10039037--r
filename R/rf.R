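# Random-forest harness on raw-acceleration epoch features.
#
# This reproduces the feature-extraction + training structure of the
# raw-acceleration random-forest approach; published forest weights are
# not redistributed, so the harness trains on user-supplied (or synthetic)
# labelled nights.

#' Extract per-epoch raw-acceleration features for the random forest
#'
#' For every 30-s epoch: per-axis mean/SD/min/max, vector-magnitude
#' mean/SD and z-angle mean/SD (16 base features), plus lagged and leading
#' copies from the adjacent -2..+2 epochs (zero-padded at the boundaries),
#' in a fixed documented column order.
#'
#' @param r a [raw_recording()] covering the grid.
#' @param grid an [epoch_grid()] anchored at the recording start.
#' @return An object of class `rf_feature_table` with fields `grid`,
#'   `feature_names` and `values` (epochs x features matrix).
#' @export
extract_rf_features <- function(r, grid) {
  stopifnot(inherits(r, "raw_recording"), inherits(grid, "epoch_grid"))
  if (abs(as_time_num(r$start_time) - as_time_num(grid$start_time)) > 1e-6)
    stopf("actisleep_alignment_error", "recording and grid must share a start time")
  fs <- r$sample_rate_hz
  spe <- round(fs * grid$epoch_length_s)
  if (n_samples(r) < spe * grid$n_epochs)
    stopf("actisleep_alignment_error", "recording does not cover the grid")
  shape <- function(v) matrix(v[seq_len(spe * grid$n_epochs)], nrow = spe)
  mx <- shape(r$ax); my <- shape(r$ay); mz <- shape(r$az)
  vm <- sqrt(mx^2 + my^2 + mz^2)
  za <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  col_sd <- function(m) sqrt(colMeans(m^2) - colMeans(m)^2) * sqrt(spe / (spe - 1))
  base <- cbind(
    ax_mean = colMeans(mx), ax_sd = col_sd(mx),
    ax_min = apply(mx, 2L, min), ax_max = apply(mx, 2L, max),
    ay_mean = colMeans(my), ay_sd = col_sd(my),
    ay_min = apply(my, 2L, min), ay_max = apply(my, 2L, max),
    az_mean = colMeans(mz), az_sd = col_sd(mz),
    az_min = apply(mz, 2L, min), az_max = apply(mz, 2L, max),
    vm_mean = colMeans(vm), vm_sd = col_sd(vm),
    zangle_mean = colMeans(za), zangle_sd = col_sd(za))
  lagged <- function(m, off) {   # value of epoch k+off, zero-padded
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- m[src[ok], , drop = FALSE]
    colnames(out) <- sprintf("%s_%s%d", colnames(m),
                             if (off < 0L) "lag" else "lead", abs(off))
    out
  }
  vals <- cbind(base, lagged(base, -2L), lagged(base, -1L),
                lagged(base, 1L), lagged(base, 2L))
  structure(list(grid = grid, feature_names = colnames(vals), values = vals),
            class = "rf_feature_table")
}

#' Train and/or apply the random-forest sleep-wake classifier
#'
#' In training mode (`truth` supplied) a seeded random forest is fitted to
#' the features and applied to them; in apply mode a previously trained
#' model is applied.  Training is reproducible given `seed`.
#'
#' @param features an [extract_rf_features()] table.
#' @param truth aligned [sleepwake()] ground truth (training mode).
#' @param model a fitted model returned by a previous call (apply mode).
#' @param ntree number of trees; default 100.
#' @param seed RNG seed for training; default 1.
#' @return a [sleepwake()] with source `"random_forest"` and the fitted
#'   model attached as attribute `"model"`.
#' @export
train_apply_rf <- function(features, truth = NULL, model = NULL,
                           ntree = 100L, seed = 1L) {
  stopifnot(inherits(features, "rf_feature_table"))
  x <- as.data.frame(features$values)
  if (is.null(model)) {
    if (is.null(truth))
      stopf("actisleep_parameter_error", "supply either truth (train) or model (apply)")
    stopifnot(inherits(truth, "sleepwake"))
    if (truth$grid$n_epochs != features$grid$n_epochs)
      stopf("actisleep_alignment_error", "truth and features must be aligned")
    y <- factor(truth$labels, levels = LABEL_LEVELS)
    if (length(unique(truth$labels)) < 2L)
      stopf("actisleep_training_error", "training labels contain a single class")
    model <- with_local_seed(seed, randomForest::randomForest(x, y, ntree = ntree))
  }
  pred <- as.character(stats::predict(model, x))
  out <- sleepwake(features$grid, pred, "random_forest")
  attr(out, "model") <- model
  out
}
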