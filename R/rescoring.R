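# Webster rescoring.
#
# Heuristic post-processing developed with the original actigraphy scoring
# algorithm: sleep scored near long wake runs is rescored as wake, to
# correct actigraphy's systematic under-detection of wake.  Only
# sleep -> wake changes are ever made, so rescoring can only lower
# sensitivity and raise specificity against any fixed truth.

#' The Webster rescoring rule set
#'
#' Default rules (durations in minutes):
#' (a) after >= 4 min wake, rescore the next 1 min of sleep as wake;
#' (b) after >= 10 min wake, the next 3 min; (c) after >= 15 min wake, the
#' next 4 min; (d) sleep bouts <= 6 min flanked by >= 10 min wake on both
#' sides become wake; (e) sleep bouts <= 10 min flanked by >= 20 min wake
#' become wake.  Rules are applied sequentially in the listed order, each
#' on the output of the previous.
#'
#' @param preset optional preset list (see [load_presets()]); defaults to
#'   the packaged rule file.
#' @return An object of class `rescore_rules`: list of rule descriptors.
#' @export
webster_rules <- function(preset = NULL) {
  if (is.null(preset)) preset <- load_presets()$webster
  rules <- preset$rules
  for (r in rules) {
    durs <- unlist(r[intersect(names(r), c("min_wake_min", "rescore_sleep_min",
                                           "max_sleep_min", "min_flank_wake_min"))])
    if (any(durs <= 0))
      stopf("actisleep_parameter_error", "rescore rule durations must be positive")
  }
  structure(rules, class = "rescore_rules")
}

apply_after_wake <- function(slp, min_wake_ep, rescore_ep) {
  r <- rle(slp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- slp
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] && r$lengths[i] >= min_wake_ep && i < length(r$lengths)) {
      # the run following a wake run is sleep by construction
      k <- min(rescore_ep, r$lengths[i + 1L])
      out[starts[i + 1L]:(starts[i + 1L] + k - 1L)] <- FALSE
    }
  }
  out
}

apply_surrounded <- function(slp, max_sleep_ep, min_flank_ep) {
  r <- rle(slp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- slp
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] <= max_sleep_ep &&
        i > 1L && i < length(r$lengths) &&
        r$lengths[i - 1L] >= min_flank_ep && r$lengths[i + 1L] >= min_flank_ep) {
      out[starts[i]:ends[i]] <- FALSE
    }
  }
  out
}

#' Apply Webster rescoring to a sleep-wake series
#'
#' @param s a [sleepwake()] on a 30-s grid.
#' @param rules a [webster_rules()] rule set (per-rule `enabled` flags are
#'   honoured); rules run in listed order on the progressively updated
#'   sequence.
#' @return a [sleepwake()] with `source = paste0(s$source, "_rescored")`.
#' @export
webster_rescore <- function(s, rules = webster_rules()) {
  stopifnot(inherits(s, "sleepwake"))
  epm <- 60L / s$grid$epoch_length_s   # epochs per minute
  slp <- is_sleep(s)
  for (r in unclass(rules)) {
    if (!isTRUE(r$enabled)) next
    slp <- switch(r$type,
      after_wake = apply_after_wake(slp, r$min_wake_min * epm,
                                    r$rescore_sleep_min * epm),
      surrounded = apply_surrounded(slp, r$max_sleep_min * epm,
                                    r$min_flank_wake_min * epm),
      stopf("actisleep_parameter_error", "unknown rescore rule type '%s'", r$type))
  }
  sleepwake_from_logical(s$grid, slp, paste0(s$source, "_rescored"))
}
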