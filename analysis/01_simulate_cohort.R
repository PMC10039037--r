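#!/usr/bin/env Rscript
# Step 1: simulate the study cohort's ground truth and materialize a small
# CSV fixture cohort.
#
# The study conditions are the synth_config() defaults: 28 subjects, one
# 8-h night each, fragmented sleep (50-min mean sleep bouts with a 5-min
# floor, 5-min mean wake bouts), moderate waking wrist movement (0.5 g)
# with posture changes every 2 min, 5% of sleep epochs disturbed by a 10-s
# movement burst, 0.01 g sensor noise, 85.7 Hz sampling.
#
# Raw acceleration is NOT written to disk here: it is fully determined by
# the seed, so step 2 regenerates it in memory subject by subject.  This
# step writes the hypnograms and their analytic endpoints, plus a 3-subject
# x 2-h CSV fixture cohort exercising the full file contract.

suppressMessages(library(actisleep))

out <- "results"
dir.create(file.path(out, "cohort"), recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 20260922L)

truth_rows <- list()
for (i in seq_len(cfg$n_subjects)) {
  gt <- gen_hypnogram(cfg, i)
  id <- sprintf("S%02d", i)
  write_hypnogram_csv(gt$hypnogram,
                      file.path(out, "cohort", sprintf("%s_hypnogram.csv", id)))
  e <- gt$endpoints
  truth_rows[[id]] <- data.frame(subject = id, waso_min = e$waso_min,
                                 tst_min = e$tst_min, se_pct = e$se_pct)
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path(out, "cohort", "truth_endpoints.csv"),
          row.names = FALSE)

write_fixture_cohort(file.path(out, "cohort_fixture"),
                     synth_config(n_subjects = 3, night_duration_min = 120,
                                  seed = cfg$seed))

cat(sprintf("simulated %d ground-truth nights (%d epochs each)\n",
            cfg$n_subjects, 2 * cfg$night_duration_min))
cat(sprintf("cohort means: TST %.0f min, WASO %.0f min, SE %.0f%%\n",
            mean(truth$tst_min), mean(truth$waso_min), mean(truth$se_pct)))
cat("hypnograms + truth endpoints under results/cohort/, fixtures under results/cohort_fixture/\n")
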