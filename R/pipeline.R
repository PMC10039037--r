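# Orchestration: run the full evaluation from a config, emit the
# per-subject predictions, the confusion-metric grid ("mean (SD)" per
# algorithm, one row per raw/rescored variant) and the Bland-Altman grid
# per sleep endpoint, plus a machine-readable manifest.  JSON reports are
# canonical; delimited-text twins are written alongside.

COUNT_ALGOS <- c("cole_kripke", "oakley", "sadeh", "sazonov", "simple_threshold")
RAW_ALGOS <- c("vanhees")
REF_ALGOS <- c("all_sleep", "all_wake")

#' Build and validate a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate the cohort) or `"directory"` (read
#'   `<id>_accel.csv` / `<id>_hypnogram.csv` pairs from `input_dir`).
#' @param synth a [synth_config()] for synthetic mode.
#' @param input_dir directory of subject files for directory mode.
#' @param algorithms algorithm names to run; defaults to all built-ins.
#' @param rescore subset of algorithms to also report Webster-rescored;
#'   defaults to the legacy count algorithms.
#' @param combine axis-combination mode for the count classifiers
#'   (see [combine_axes()]).
#' @param sens_min,spec_min selection thresholds in percent.
#' @param onset_rule endpoint onset rule (see [endpoints()]).
#' @param preset_overrides overrides passed to [load_presets()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed master seed (forwarded to the synthetic generator).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       synth = synth_config(), input_dir = NULL,
                       algorithms = c(COUNT_ALGOS, RAW_ALGOS, REF_ALGOS),
                       rescore = c("cole_kripke", "oakley", "sadeh", "sazonov"),
                       combine = "vector_magnitude",
                       sens_min = 75, spec_min = 45,
                       onset_rule = list(consecutive_epochs = 1L),
                       preset_overrides = list(),
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  known <- c(COUNT_ALGOS, RAW_ALGOS, REF_ALGOS)
  bad <- setdiff(algorithms, known)
  if (length(bad))
    stopf("actisleep_parameter_error", "unknown algorithm(s): %s",
          paste(bad, collapse = ", "))
  bad <- setdiff(rescore, algorithms)
  if (length(bad))
    stopf("actisleep_parameter_error", "rescore names not in algorithm list: %s",
          paste(bad, collapse = ", "))
  if (mode == "directory" && (is.null(input_dir) || !dir.exists(input_dir)))
    stopf("actisleep_parameter_error", "directory mode needs an existing input_dir")
  if (mode == "synthetic") synth$seed <- as.integer(seed)
  structure(list(mode = mode, synth = synth, input_dir = input_dir,
                 algorithms = algorithms, rescore = rescore, combine = combine,
                 sens_min = sens_min, spec_min = spec_min,
                 onset_rule = onset_rule, preset_overrides = preset_overrides,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# one thunk per subject so only a single night's raw data is in memory
# at a time; a thunk returns NULL (with a warning) for unreadable subjects
subject_loaders <- function(cfg) {
  if (cfg$mode == "synthetic") {
    lapply(seq_len(cfg$synth$n_subjects), function(i) {
      force(i)
      function() {
        gt <- gen_hypnogram(cfg$synth, i)
        rec <- gen_accel(gt, cfg$synth)
        list(id = rec$subject_id, recording = rec, hypnogram = gt$hypnogram)
      }
    })
  } else {
    acc <- sort(list.files(cfg$input_dir, pattern = "_accel\\.csv$",
                           full.names = TRUE))
    lapply(acc, function(f) {
      force(f)
      function() {
        id <- sub("_accel\\.csv$", "", basename(f))
        hf <- file.path(cfg$input_dir, paste0(id, "_hypnogram.csv"))
        tryCatch(list(id = id,
                      recording = read_accel_csv(f, subject_id = id),
                      hypnogram = read_hypnogram_csv(hf)),
                 error = function(e) {
                   warning(sprintf("skipping subject %s: %s", id,
                                   conditionMessage(e)))
                   NULL
                 })
      }
    })
  }
}

classify_subject <- function(sub, cfg, presets) {
  truth_full <- binarize_hypnogram(sub$hypnogram)
  preds <- list()
  run_counts <- length(intersect(cfg$algorithms, COUNT_ALGOS)) > 0L
  if (run_counts) {
    r40 <- downsample_mean(sub$recording)
    cts <- compute_counts(r40)
    combined <- combine_axes(cts, cfg$combine)
    cgrid <- cts$grid
    for (a in intersect(cfg$algorithms, COUNT_ALGOS)) {
      preds[[a]] <- switch(a,
        cole_kripke = classify_linear_window(
          combined, linear_window_model(presets$cole_kripke, "cole_kripke"), cgrid),
        oakley = classify_linear_window(
          combined, linear_window_model(presets$oakley, "oakley"), cgrid),
        simple_threshold = classify_linear_window(
          combined, linear_window_model(presets$simple_threshold, "simple_threshold"),
          cgrid),
        sadeh = classify_sadeh(combined, presets$sadeh, cgrid),
        sazonov = classify_sazonov(combined, presets$sazonov, cgrid))
    }
  }
  if ("vanhees" %in% cfg$algorithms) {
    ang <- compute_z_angle(sub$recording, presets$vanhees)
    nblk <- length(ang)
    nep <- floor(nblk * attr(ang, "block_s") / truth_full$grid$epoch_length_s)
    vgrid <- epoch_grid(truth_full$grid$start_time, nep,
                        truth_full$grid$epoch_length_s)
    preds$vanhees <- classify_vanhees(ang, presets$vanhees, vgrid)
  }
  for (a in intersect(cfg$algorithms, REF_ALGOS))
    preds[[a]] <- reference_classifier(truth_full$grid, a)
  rules <- webster_rules(presets$webster)
  for (a in intersect(cfg$rescore, names(preds)))
    preds[[paste0(a, "_rescored")]] <- webster_rescore(preds[[a]], rules)
  list(truth = truth_full, preds = preds)
}

#' Run the full evaluation pipeline
#'
#' For every subject: activity counts, predictions from every configured
#' algorithm (plus Webster-rescored variants of the legacy count
#' algorithms), per-subject confusion statistics and sleep endpoints.
#' Across the cohort: the per-algorithm "mean (SD)" confusion grid, the
#' Bland-Altman grid for WASO/TST/SE against the PSG-derived values, and
#' the sensitivity/specificity selection rule.  Identical config and seed
#' give identical outputs.
#'
#' @param cfg a [run_config()].
#' @return list with `table1` (data.frame), `table2` (data.frame),
#'   `selected` (character), `per_subject`, `summaries`, `manifest`;
#'   written under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  presets <- load_presets(overrides = cfg$preset_overrides)
  loaders <- subject_loaders(cfg)

  per_subject <- list()
  for (ld in loaders) {
    sub <- ld()
    if (is.null(sub)) next
    res <- classify_subject(sub, cfg, presets)
    entry <- list(id = sub$id, truth = res$truth, preds = res$preds,
                  stats = list(), endpoints = list(),
                  truth_endpoints = NULL)
    for (a in names(res$preds)) {
      p <- align_to_grid(res$preds[[a]], res$truth$grid)
      t <- align_to_grid(res$truth, p$grid)
      entry$stats[[a]] <- confusion(p, t)
      entry$endpoints[[a]] <- endpoints(p, onset_rule = cfg$onset_rule)
      if (is.null(entry$truth_endpoints))
        entry$truth_endpoints <- endpoints(t, onset_rule = cfg$onset_rule)
    }
    per_subject[[sub$id]] <- entry
  }
  if (!length(per_subject))
    stopf("actisleep_parameter_error", "empty cohort")

  algo_names <- names(per_subject[[1L]]$stats)
  summaries <- lapply(algo_names, function(a)
    cohort_aggregate(lapply(per_subject, function(e) e$stats[[a]]), a))
  names(summaries) <- algo_names
  selected <- select_algorithms(summaries, cfg$sens_min, cfg$spec_min)
  sel_names <- unname(vapply(selected, `[[`, character(1L), "algorithm"))
  for (a in sel_names) summaries[[a]]$selected <- TRUE
  for (a in setdiff(algo_names, sel_names)) summaries[[a]]$selected <- FALSE

  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  table1 <- data.frame(algorithm = algo_names,
                       do.call(rbind, lapply(summaries, function(s)
                         stats::setNames(as.data.frame(t(s$mean)), metrics))),
                       selected = algo_names %in% sel_names,
                       row.names = NULL, check.names = FALSE)

  eps <- c("waso_min", "tst_min", "se_pct")
  rows <- list()
  for (a in algo_names) for (ep in eps) {
    pv <- vapply(per_subject, function(e) e$endpoints[[a]][[ep]], numeric(1L))
    tv <- vapply(per_subject, function(e) e$truth_endpoints[[ep]], numeric(1L))
    ba <- if (any(!is.na(pv) & !is.na(tv))) bland_altman(pv, tv)
          else list(n = 0L, me = NA_real_, rmse = NA_real_, pearson_r = NA_real_,
                    loa_upper = NA_real_, loa_lower = NA_real_, ci_width = NA_real_)
    rows[[paste(a, ep)]] <- data.frame(
      algorithm = a, endpoint = ep, n = ba$n, me = ba$me, rmse = ba$rmse,
      correlation = ba$pearson_r, loa_upper = ba$loa_upper,
      loa_lower = ba$loa_lower, ci_width = ba$ci_width)
  }
  table2 <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("actisleep")),
    preset_version = presets$version,
    seed = cfg$seed, mode = cfg$mode, combine = cfg$combine,
    algorithms = cfg$algorithms, rescore = cfg$rescore,
    sens_min = cfg$sens_min, spec_min = cfg$spec_min,
    n_subjects = length(per_subject),
    config_hash = config_hash(cfg))

  out <- list(table1 = table1, table2 = table2, selected = sel_names,
              summaries = summaries, per_subject = per_subject,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_reports(out, cfg)
  out
}

# order-invariant content hash of the analysis-defining config fields
# (output location excluded), dependency-free
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  raw <- serialize(cfg[order(names(cfg))], NULL, version = 2L)
  sum_a <- 1; sum_b <- 0
  v <- as.integer(raw)
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    sum_a <- (sum_a + sum(chunk)) %% 65521
    sum_b <- (sum_b + sum(cumsum(chunk))) %% 65521
  }
  sprintf("%04x%04x", as.integer(sum_b), as.integer(sum_a))
}

write_reports <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pred_dir <- file.path(cfg$out_dir, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  for (e in out$per_subject) {
    for (a in names(e$preds))
      write_sleepwake_csv(e$preds[[a]],
                          file.path(pred_dir, sprintf("%s_%s.csv", e$id, a)))
    write_sleepwake_csv(e$truth, file.path(pred_dir, sprintf("%s_PSG.csv", e$id)))
  }
  data.table::fwrite(out$table1, file.path(cfg$out_dir, "table1_confusion.csv"))
  data.table::fwrite(out$table2, file.path(cfg$out_dir, "table2_bland_altman.csv"))
  jsonlite::write_json(
    list(table1 = out$table1, table2 = out$table2,
         selected = out$selected, manifest = out$manifest),
    file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

#' Read back a structured pipeline report
#' @param path `report.json` written by [run_pipeline()].
#' @return list with `table1`, `table2`, `selected`, `manifest`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
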