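#' @keywords internal
"_PACKAGE"

# ---- internal helpers -------------------------------------------------------

as_time_num <- function(t) {
  if (inherits(t, "POSIXct")) return(as.numeric(t))
  if (is.numeric(t)) return(as.numeric(t))
  stop("timestamp must be POSIXct or numeric seconds", call. = FALSE)
}

as_time_posix <- function(t) {
  if (inherits(t, "POSIXct")) return(t)
  as.POSIXct(t, origin = "1970-01-01", tz = "UTC")
}

stopf <- function(cls, fmt, ...) {
  stop(structure(class = c(cls, "actisleep_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM")
LABEL_LEVELS <- c("wake", "sleep")

# ---- RawRecording -----------------------------------------------------------

#' Uniformly sampled tri-axial wrist acceleration
#'
#' Container for a raw acceleration recording in units of gravity (g),
#' sampled at a single fixed rate.
#'
#' @param subject_id character scalar identifying the wearer.
#' @param start_time `POSIXct` (or numeric epoch seconds) of the first sample.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param ax,ay,az numeric vectors of equal length: acceleration in g.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(subject_id, start_time, sample_rate_hz, ax, ay, az) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stopf("actisleep_parameter_error", "sample_rate_hz must be a positive finite number")
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n)
    stopf("actisleep_format_error",
          "axis sequences must have identical length >= 1 (got %d, %d, %d)",
          length(ax), length(ay), length(az))
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stopf("actisleep_data_error", "acceleration values must all be finite")
  structure(list(subject_id = subject_id,
                 start_time = as_time_posix(start_time),
                 sample_rate_hz = sample_rate_hz,
                 ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d samples @ %.6g Hz (%.1f min) from %s\n",
              x$subject_id, length(x$ax), x$sample_rate_hz,
              length(x$ax) / x$sample_rate_hz / 60,
              format(x$start_time, "%Y-%m-%d %H:%M:%OS2", tz = "UTC")))
  invisible(x)
}

n_samples <- function(r) length(r$ax)

# ---- EpochGrid --------------------------------------------------------------

#' Non-overlapping epoch grid
#'
#' Defines the fixed grid of half-open windows `[t, t + epoch_length_s)`
#' on which sleep-wake labels and activity counts live.  The epoch length
#' must divide 60 s so that per-minute aggregation is exact.
#'
#' @param start_time `POSIXct` or numeric epoch seconds of the first epoch.
#' @param n_epochs nonnegative integer number of epochs.
#' @param epoch_length_s positive integer dividing 60; default 30.
#' @return An object of class `epoch_grid`.
#' @export
epoch_grid <- function(start_time, n_epochs, epoch_length_s = 30L) {
  epoch_length_s <- as.integer(epoch_length_s)
  if (is.na(epoch_length_s) || epoch_length_s <= 0L || 60L %% epoch_length_s != 0L)
    stopf("actisleep_parameter_error",
          "epoch_length_s must be a positive integer dividing 60 (got %s)",
          as.character(epoch_length_s))
  n_epochs <- as.integer(n_epochs)
  if (is.na(n_epochs) || n_epochs < 0L)
    stopf("actisleep_parameter_error", "n_epochs must be a nonnegative integer")
  structure(list(start_time = as_time_posix(start_time),
                 epoch_length_s = epoch_length_s,
                 n_epochs = n_epochs),
            class = "epoch_grid")
}

#' Epoch start times of a grid
#' @param g an `epoch_grid`.
#' @return numeric vector of epoch start times (seconds since 1970).
#' @export
grid_times <- function(g) {
  as_time_num(g$start_time) + (seq_len(g$n_epochs) - 1L) * g$epoch_length_s
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d x %ds epochs from %s\n", x$n_epochs,
              x$epoch_length_s, format(x$start_time, tz = "UTC")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  a$epoch_length_s == b$epoch_length_s && a$n_epochs == b$n_epochs &&
    abs(as_time_num(a$start_time) - as_time_num(b$start_time)) < tol
}

# ---- Hypnogram --------------------------------------------------------------

#' PSG hypnogram on an epoch grid
#'
#' @param grid an `epoch_grid`.
#' @param stages character vector of stage labels in `W, N1, N2, N3, REM`,
#'   one per grid epoch.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(grid, stages) {
  stopifnot(inherits(grid, "epoch_grid"))
  stages <- as.character(stages)
  if (length(stages) != grid$n_epochs)
    stopf("actisleep_format_error", "need %d stages, got %d",
          grid$n_epochs, length(stages))
  bad <- which(!(stages %in% STAGE_LEVELS))
  if (length(bad))
    stopf("actisleep_format_error", "unknown stage label '%s' at row %d",
          stages[bad[1L]], bad[1L])
  structure(list(grid = grid, stages = stages), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs: %s\n", x$grid$n_epochs,
              paste(sprintf("%s=%d", names(table(x$stages)), table(x$stages)),
                    collapse = " ")))
  invisible(x)
}

# ---- SleepWakeSeries --------------------------------------------------------

#' Binary sleep-wake label series on an epoch grid
#'
#' @param grid an `epoch_grid`.
#' @param labels character vector of `"sleep"` / `"wake"`, one per epoch.
#' @param source character scalar naming the producer (algorithm name or `"PSG"`).
#' @return An object of class `sleepwake`.
#' @export
sleepwake <- function(grid, labels, source) {
  stopifnot(inherits(grid, "epoch_grid"), is.character(source), length(source) == 1L)
  labels <- as.character(labels)
  if (length(labels) != grid$n_epochs)
    stopf("actisleep_format_error", "need %d labels, got %d",
          grid$n_epochs, length(labels))
  bad <- which(!(labels %in% LABEL_LEVELS))
  if (length(bad))
    stopf("actisleep_format_error", "labels must be 'sleep'/'wake'; got '%s' at %d",
          labels[bad[1L]], bad[1L])
  structure(list(grid = grid, labels = labels, source = source),
            class = "sleepwake")
}

#' Logical sleep indicator of a sleep-wake series
#' @param s a `sleepwake` object.
#' @return logical vector, `TRUE` for sleep epochs.
#' @export
is_sleep <- function(s) s$labels == "sleep"

#' Build a sleep-wake series from a logical sleep indicator
#' @param grid an `epoch_grid`.
#' @param sleep logical vector (`TRUE` = sleep).
#' @param source producer name.
#' @return a `sleepwake` object.
#' @export
sleepwake_from_logical <- function(grid, sleep, source) {
  sleepwake(grid, ifelse(sleep, "sleep", "wake"), source)
}

#' @export
print.sleepwake <- function(x, ...) {
  cat(sprintf("<sleepwake> %s: %d epochs, %d sleep / %d wake\n", x$source,
              x$grid$n_epochs, sum(is_sleep(x)), sum(!is_sleep(x))))
  invisible(x)
}

#' Collapse a hypnogram to binary sleep-wake
#'
#' `W` maps to wake; `N1`, `N2`, `N3` and `REM` all map to sleep.  The
#' result carries source `"PSG"` and is the ground-truth series against
#' which classifier output is scored.
#'
#' @param h a `hypnogram`.
#' @return a `sleepwake` with source `"PSG"`.
#' @export
binarize_hypnogram <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  sleepwake(h$grid, ifelse(h$stages == "W", "wake", "sleep"), "PSG")
}

# ---- delimited-text readers / writers ---------------------------------------

parse_time_col <- function(x, what = "timestamp") {
  if (is.numeric(x)) return(as.numeric(x))
  xn <- suppressWarnings(as.numeric(x))
  if (!anyNA(xn)) return(xn)
  tt <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  if (anyNA(tt)) tt <- as.POSIXct(x, tz = "UTC")
  if (anyNA(tt))
    stopf("actisleep_format_error", "cannot parse %s column as numeric or ISO-8601", what)
  as.numeric(tt)
}

#' Read raw acceleration from delimited text
#'
#' Expects a timestamp column (ISO-8601 or numeric epoch seconds) and three
#' numeric axis columns in g.  The sample rate is inferred from the median
#' timestamp spacing; no samples are dropped.  Recordings with internal gaps
#' (spacing more than twice the sample interval) are rejected.
#'
#' @param path file to read.
#' @param col_map named list overriding defaults
#'   `list(timestamp = "timestamp", x = "x", y = "y", z = "z", sep = ",")`.
#' @param subject_id subject identifier; default the file name.
#' @return a [raw_recording()].
#' @export
read_accel_csv <- function(path, col_map = list(), subject_id = NULL) {
  cm <- utils::modifyList(list(timestamp = "timestamp", x = "x", y = "y",
                               z = "z", sep = ","), col_map)
  if (!file.exists(path))
    stopf("actisleep_format_error", "file not found: %s", path)
  d <- data.table::fread(path, sep = cm$sep, header = TRUE, data.table = FALSE)
  need <- c(cm$timestamp, cm$x, cm$y, cm$z)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("actisleep_format_error", "missing columns: %s", paste(miss, collapse = ", "))
  tt <- parse_time_col(d[[cm$timestamp]])
  if (length(tt) >= 2L) {
    dt <- diff(tt)
    if (any(dt <= 0))
      stopf("actisleep_data_error", "timestamps not monotone increasing (first violation at row %d)",
            which(dt <= 0)[1L] + 1L)
    med <- stats::median(dt)
    gaps <- which(dt > 2 * med)
    if (length(gaps))
      stopf("actisleep_gap_error", "gap(s) > 2x sample interval after row(s): %s",
            paste(utils::head(gaps, 10L), collapse = ", "))
    # the covered span is robust to per-timestamp quantization
    rate <- (length(tt) - 1L) / (tt[length(tt)] - tt[1L])
  } else rate <- NA_real_
  if (is.null(subject_id)) subject_id <- basename(path)
  raw_recording(subject_id, tt[1L],
                if (is.na(rate)) 1 else rate,
                as.numeric(d[[cm$x]]), as.numeric(d[[cm$y]]), as.numeric(d[[cm$z]]))
}

#' Write raw acceleration to delimited text
#'
#' Timestamps are written as numeric epoch seconds at microsecond precision
#' so that a write/read round trip is value-identical.
#'
#' @param r a [raw_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(r, path) {
  stopifnot(inherits(r, "raw_recording"))
  t0 <- as_time_num(r$start_time)
  tt <- t0 + (seq_len(n_samples(r)) - 1L) / r$sample_rate_hz
  d <- data.frame(timestamp = sprintf("%.6f", tt),
                  x = r$ax, y = r$ay, z = r$az)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read a hypnogram from delimited text
#'
#' One row per 30-s epoch with columns `timestamp` and `stage`
#' (`W/N1/N2/N3/REM`).  The grid starts at the first row's timestamp.
#'
#' @param path file to read.
#' @param epoch_length_s epoch length in seconds; default 30.
#' @return a [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, epoch_length_s = 30L) {
  if (!file.exists(path))
    stopf("actisleep_format_error", "file not found: %s", path)
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("timestamp", "stage") %in% names(d)))
    stopf("actisleep_format_error", "hypnogram file needs columns timestamp, stage")
  st <- as.character(d$stage)
  bad <- which(!(st %in% STAGE_LEVELS))
  if (length(bad))
    stopf("actisleep_format_error", "unknown stage label '%s' at row %d",
          st[bad[1L]], bad[1L])
  tt <- parse_time_col(d$timestamp)
  hypnogram(epoch_grid(tt[1L], nrow(d), epoch_length_s), st)
}

#' Write a hypnogram to delimited text
#' @param h a [hypnogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  d <- data.frame(timestamp = sprintf("%.6f", grid_times(h$grid)), stage = h$stages)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Write a sleep-wake series to delimited text
#' @param s a [sleepwake()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sleepwake_csv <- function(s, path) {
  stopifnot(inherits(s, "sleepwake"))
  d <- data.frame(timestamp = sprintf("%.6f", grid_times(s$grid)),
                  label = s$labels, source = s$source)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read a sleep-wake series from delimited text
#' @param path file with columns timestamp, label, source.
#' @param epoch_length_s epoch length in seconds; default 30.
#' @return a [sleepwake()].
#' @export
read_sleepwake_csv <- function(path, epoch_length_s = 30L) {
  d <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("timestamp", "label") %in% names(d)))
    stopf("actisleep_format_error", "sleep-wake file needs columns timestamp, label")
  tt <- parse_time_col(d$timestamp)
  src <- if ("source" %in% names(d)) as.character(d$source[1L]) else "unknown"
  sleepwake(epoch_grid(tt[1L], nrow(d), epoch_length_s), as.character(d$label), src)
}

# ---- downsampling -----------------------------------------------------------

#' Downsample a raw recording by window means
#'
#' Each output sample is the arithmetic mean of the input samples whose
#' timestamps fall in the corresponding half-open window of `window_ms`
#' milliseconds; the output rate is `target_rate_hz`.  A trailing window not
#' fully covered by the input is dropped.  This is the standard reduction of
#' 85.7 Hz wrist data to the 40 Hz input of the activity-count stage.
#'
#' @param r a [raw_recording()].
#' @param target_rate_hz output rate; default 40.
#' @param window_ms averaging window; default 25 (= 1/40 s).
#' @return a [raw_recording()] at `target_rate_hz`.
#' @export
downsample_mean <- function(r, target_rate_hz = 40, window_ms = 25) {
  stopifnot(inherits(r, "raw_recording"))
  if (target_rate_hz > r$sample_rate_hz)
    stopf("actisleep_parameter_error",
          "cannot upsample: input rate %.4g Hz < target %.4g Hz",
          r$sample_rate_hz, target_rate_hz)
  if (abs(r$sample_rate_hz - target_rate_hz) < 1e-9) return(r)
  w <- window_ms / 1000
  n <- n_samples(r)
  tt <- (seq_len(n) - 1L) / r$sample_rate_hz
  duration <- n / r$sample_rate_hz
  n_out <- floor(duration / w + 1e-9)
  if (n_out < 1L)
    stopf("actisleep_parameter_error", "recording shorter than one window")
  idx <- floor(tt / w + 1e-9) + 1L          # window index per sample
  keep <- idx <= n_out
  idx <- idx[keep]
  cnt <- tabulate(idx, nbins = n_out)
  mean_by <- function(v) {
    s <- rowsum(v[keep], idx, reorder = TRUE)
    as.numeric(s) / cnt
  }
  raw_recording(r$subject_id, r$start_time, target_rate_hz,
                mean_by(r$ax), mean_by(r$ay), mean_by(r$az))
}

# ---- grid alignment ---------------------------------------------------------

#' Align an epoch-labelled series to a target grid
#'
#' Keeps the epochs whose start timestamps are shared between the series'
#' own grid and `g`; epochs outside the overlap are dropped.  Works for
#' both `sleepwake` and `hypnogram` objects and returns the same type on
#' the overlapping sub-grid.
#'
#' @param s a [sleepwake()] or [hypnogram()].
#' @param g target [epoch_grid()].
#' @return the same type as `s`, restricted to the overlap with `g`.
#' @export
align_to_grid <- function(s, g) {
  stopifnot(inherits(g, "epoch_grid"))
  sg <- s$grid
  if (sg$epoch_length_s != g$epoch_length_s)
    stopf("actisleep_alignment_error", "epoch lengths differ (%d vs %d)",
          sg$epoch_length_s, g$epoch_length_s)
  ts <- round(grid_times(sg), 3)
  tg <- round(grid_times(g), 3)
  keep <- ts %in% tg
  if (!any(keep))
    stopf("actisleep_alignment_error", "series and grid do not overlap in time")
  first <- which(keep)[1L]
  ng <- epoch_grid(ts[first], sum(keep), g$epoch_length_s)
  if (inherits(s, "sleepwake")) {
    sleepwake(ng, s$labels[keep], s$source)
  } else if (inherits(s, "hypnogram")) {
    hypnogram(ng, s$stages[keep])
  } else stopf("actisleep_parameter_error", "unsupported type for align_to_grid")
}
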