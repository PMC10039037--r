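# Per-subject confusion statistics, sleep endpoints, cohort aggregation,
# Bland-Altman agreement and the selection rule.
#
# Sleep is the positive class throughout.  Metrics with a zero denominator
# are flagged NA (undefined), never silently 0; the single exception is F1,
# which is defined as 0 when there are no true positives but some
# disagreement exists (the standard convention, and the value the all-wake
# reference row takes).

#' Per-subject confusion statistics
#'
#' An epoch is TP if both truth and prediction score sleep, TN if both
#' score wake, FP if truth is wake but the prediction sleep, FN if truth is
#' sleep but the prediction wake.  Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP),
#' F1 = 2*precision*sensitivity/(precision+sensitivity),
#' accuracy = (TP+TN)/total, all as percentages.
#'
#' @param pred predicted [sleepwake()].
#' @param truth ground-truth [sleepwake()] of equal length (PSG).
#' @return An object of class `confusion_stats` with fields `tp`, `tn`,
#'   `fp`, `fn`, `n`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1` (percent; NA where undefined).
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "sleepwake"), inherits(truth, "sleepwake"))
  if (pred$grid$n_epochs != truth$grid$n_epochs)
    stopf("actisleep_alignment_error", "prediction (%d) and truth (%d) differ in length",
          pred$grid$n_epochs, truth$grid$n_epochs)
  p <- is_sleep(pred); t <- is_sleep(truth)
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  n <- tp + tn + fp + fn
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  acc <- ratio(tp + tn, n)
  f1 <- if (tp > 0) 2 * prec * sens / (prec + sens)
        else if (fp + fn > 0) 0 else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(paste0("<confusion_stats> n=%d TP=%d TN=%d FP=%d FN=%d | ",
                     "acc %.1f sens %.1f spec %.1f prec %.1f F1 %.1f\n"),
              x$n, x$tp, x$tn, x$fp, x$fn,
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Sleep endpoints of a night
#'
#' Sleep onset is the first epoch satisfying the onset rule (default: the
#' first sleep epoch; alternatively the first of `consecutive_epochs`
#' consecutive sleep epochs), offset the last sleep epoch.  WASO is the
#' wake time between onset and offset, TST the total sleep time, and SE
#' the percentage of the annotated period scored sleep.
#'
#' @param s a [sleepwake()].
#' @param annotated_epochs denominator of sleep efficiency; defaults to the
#'   series length (the period with PSG annotations).
#' @param onset_rule list with `consecutive_epochs` (default 1).
#' @return An object of class `sleep_endpoints` with `waso_min`, `tst_min`,
#'   `se_pct`, `onset_epoch`, `offset_epoch` (1-based; NA when undefined).
#' @export
endpoints <- function(s, annotated_epochs = NULL, onset_rule = list(consecutive_epochs = 1L)) {
  stopifnot(inherits(s, "sleepwake"))
  n <- s$grid$n_epochs
  if (is.null(annotated_epochs)) annotated_epochs <- n
  epm <- s$grid$epoch_length_s / 60
  slp <- is_sleep(s)
  k <- onset_rule$consecutive_epochs %||% 1L
  tst <- sum(slp) * epm
  se <- 100 * sum(slp) / annotated_epochs
  onset <- NA_integer_
  if (any(slp)) {
    runs <- rle(slp)
    ends <- cumsum(runs$lengths)
    cand <- which(runs$values & runs$lengths >= k)
    if (length(cand)) onset <- ends[cand[1L]] - runs$lengths[cand[1L]] + 1L
  }
  if (is.na(onset)) {
    out <- list(waso_min = NA_real_, tst_min = tst, se_pct = se,
                onset_epoch = NA_integer_, offset_epoch = NA_integer_)
  } else {
    offset <- max(which(slp))
    waso <- sum(!slp[onset:offset]) * epm
    out <- list(waso_min = waso, tst_min = tst, se_pct = se,
                onset_epoch = onset, offset_epoch = offset)
  }
  structure(out, class = "sleep_endpoints")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sleep_endpoints <- function(x, ...) {
  cat(sprintf("<sleep_endpoints> WASO %.1f min, TST %.1f min, SE %.1f%%\n",
              x$waso_min, x$tst_min, x$se_pct))
  invisible(x)
}

#' Aggregate per-subject confusion statistics over a cohort
#'
#' Statistics are computed for each subject and then averaged (unweighted
#' mean and sample SD across subjects).  Undefined per-subject metrics are
#' excluded pairwise, with the number of contributing subjects reported.
#'
#' @param per_subject list of [confusion()] results (>= 1).
#' @param algorithm algorithm name carried into the summary.
#' @return An object of class `cohort_summary` with `mean`, `sd`,
#'   `n_defined` per metric, `formatted` "mean (SD)" strings, and a
#'   `selected` flag (set by [select_algorithms()]).
#' @export
cohort_aggregate <- function(per_subject, algorithm = "algorithm") {
  if (!length(per_subject))
    stopf("actisleep_parameter_error", "empty cohort")
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  m <- vapply(per_subject, function(cs) unlist(cs[metrics]), numeric(5L))
  m <- matrix(m, nrow = length(metrics),
              dimnames = list(metrics, NULL))
  mu <- apply(m, 1L, mean, na.rm = TRUE)
  sdv <- apply(m, 1L, function(v) if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0)
  nd <- apply(m, 1L, function(v) sum(!is.na(v)))
  mu[nd == 0L] <- NA_real_
  structure(list(algorithm = algorithm, n_subjects = length(per_subject),
                 mean = mu, sd = sdv, n_defined = nd,
                 formatted = sprintf("%.1f (%.1f)", mu, sdv),
                 selected = NA),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n=%d)%s\n", x$algorithm, x$n_subjects,
              if (isTRUE(x$selected)) " [selected]" else ""))
  print(stats::setNames(x$formatted, names(x$mean)))
  invisible(x)
}

#' Bland-Altman agreement between predicted and reference endpoints
#'
#' With differences `d_i = pred_i - truth_i`: mean error `ME = mean(d)`,
#' `RMSE = sqrt(mean(d^2))`, Pearson correlation between the paired
#' vectors, limits of agreement `ME +- 1.96 * SD(d)` (sample SD) and their
#' width.  Dispersion terms require n >= 2 and are NA otherwise; the
#' correlation is NA when either vector has zero variance.
#'
#' @param pred_endpoint numeric per-subject predicted endpoint values.
#' @param truth_endpoint numeric per-subject reference values, same length.
#' @return An object of class `agreement_stats` with `me`, `rmse`,
#'   `pearson_r`, `loa_upper`, `loa_lower`, `ci_width`, `n`.
#' @export
bland_altman <- function(pred_endpoint, truth_endpoint) {
  if (length(pred_endpoint) != length(truth_endpoint))
    stopf("actisleep_alignment_error", "endpoint vectors must be paired")
  ok <- !is.na(pred_endpoint) & !is.na(truth_endpoint)
  p <- pred_endpoint[ok]; t <- truth_endpoint[ok]
  n <- length(p)
  if (n < 1L) stopf("actisleep_parameter_error", "no complete endpoint pairs")
  d <- p - t
  me <- mean(d)
  rmse <- sqrt(mean(d^2))
  if (n >= 2L) {
    sdd <- stats::sd(d)
    loa_u <- me + 1.96 * sdd
    loa_l <- me - 1.96 * sdd
    ciw <- loa_u - loa_l
    r <- if (stats::sd(p) > 0 && stats::sd(t) > 0) stats::cor(p, t) else NA_real_
  } else {
    loa_u <- loa_l <- ciw <- r <- NA_real_
  }
  structure(list(me = me, rmse = rmse, pearson_r = r,
                 loa_upper = loa_u, loa_lower = loa_l, ci_width = ciw, n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n=%d ME %.2f RMSE %.2f r %.3f LoA [%.2f, %.2f]\n",
              x$n, x$me, x$rmse, x$pearson_r, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Select algorithms passing minimal sensitivity and specificity
#'
#' Retains the summaries whose cohort-mean sensitivity and specificity meet
#' the thresholds (defaults 75% and 45%) and sets their `selected` flag.
#'
#' @param summaries list of [cohort_aggregate()] results.
#' @param sens_min minimum mean sensitivity in percent; default 75.
#' @param spec_min minimum mean specificity in percent; default 45.
#' @return list of the selected `cohort_summary` objects, each with
#'   `selected = TRUE`.
#' @export
select_algorithms <- function(summaries, sens_min = 75, spec_min = 45) {
  keep <- vapply(summaries, function(s) {
    isTRUE(s$mean[["sensitivity"]] >= sens_min && s$mean[["specificity"]] >= spec_min)
  }, logical(1L))
  lapply(summaries[keep], function(s) { s$selected <- TRUE; s })
}
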