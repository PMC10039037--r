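# Loading and validation of the versioned classifier parameter file.

#' Load the versioned algorithm parameter presets
#'
#' Presets for the legacy classifiers ship in a YAML file under
#' `inst/extdata/algorithm-presets.yaml`; each entry cites the publication
#' its constants come from.  Individual values can be overridden without
#' editing the file.
#'
#' @param path preset file; defaults to the copy installed with the package.
#' @param overrides nested named list merged over the file contents, e.g.
#'   `list(oakley = list(threshold = 20))`.
#' @return named list of presets with a `version` field.
#' @export
load_presets <- function(path = system.file("extdata", "algorithm-presets.yaml",
                                            package = "actisleep"),
                         overrides = list()) {
  p <- yaml::read_yaml(path)
  if (is.null(p$version))
    stopf("actisleep_format_error", "preset file lacks a version field")
  need <- c("cole_kripke", "oakley", "sadeh", "sazonov", "simple_threshold",
            "vanhees", "webster")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stopf("actisleep_format_error", "preset file missing sections: %s",
          paste(miss, collapse = ", "))
  p <- utils::modifyList(p, overrides)
  validate_presets(p)
  p
}

validate_presets <- function(p) {
  for (nm in c("cole_kripke", "oakley", "simple_threshold")) {
    m <- p[[nm]]
    if (!length(m$weights)) stopf("actisleep_format_error", "%s: empty weights", nm)
    if (!is.finite(m$threshold)) stopf("actisleep_format_error", "%s: bad threshold", nm)
    if (!m$sleep_when %in% c("score_below", "score_at_or_below"))
      stopf("actisleep_format_error", "%s: bad sleep_when '%s'", nm, m$sleep_when)
    if (!m$epoch_basis_s %in% c(30, 60))
      stopf("actisleep_format_error", "%s: epoch_basis_s must be 30 or 60", nm)
  }
  s <- p$sadeh
  if (!(s$nat_low < s$nat_high))
    stopf("actisleep_format_error", "sadeh: nat_low must be < nat_high")
  if (s$window_epochs_each_side < 1 || s$sd_window_epochs < 1)
    stopf("actisleep_format_error", "sadeh: window sizes must be >= 1")
  z <- p$sazonov
  if (!length(z$window_weights))
    stopf("actisleep_format_error", "sazonov: needs at least one window weight")
  if (z$probability_threshold <= 0 || z$probability_threshold >= 1)
    stopf("actisleep_format_error", "sazonov: probability_threshold must be in (0,1)")
  v <- p$vanhees
  if (any(unlist(v[c("median_window_s", "angle_block_s",
                     "angle_change_threshold_deg", "min_still_duration_min")]) <= 0))
    stopf("actisleep_format_error", "vanhees: parameters must be positive")
  if (v$min_still_duration_min < v$angle_block_s / 60)
    stopf("actisleep_format_error", "vanhees: min_still_duration_min too small")
  invisible(p)
}

#' Build a linear window model from a preset entry
#' @param preset a preset list entry (e.g. `load_presets()$cole_kripke`).
#' @param name model name used as prediction source.
#' @return a `linear_window_model` usable with [classify_linear_window()].
#' @export
linear_window_model <- function(preset, name) {
  w <- unlist(preset$weights)
  offs <- as.integer(names(w))
  if (anyNA(offs)) stopf("actisleep_format_error", "weight names must be integer offsets")
  structure(list(name = name, offsets = offs, weights = as.numeric(w),
                 scale = preset$scale, threshold = preset$threshold,
                 sleep_when = preset$sleep_when,
                 epoch_basis_s = as.integer(preset$epoch_basis_s)),
            class = "linear_window_model")
}
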