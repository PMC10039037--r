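Package: actisleep
Title: Actigraphy Sleep-Wake Classification from Raw Wrist Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete actigraphy sleep-analysis toolkit: derives activity
    counts from raw tri-axial wrist acceleration (anti-aliased resampling,
    legacy band-pass emulation, rectification, dead-band and saturation,
    fixed-resolution quantization, per-epoch accumulation), implements the
    classic count-based sleep-wake classifiers (Cole-Kripke, Sadeh, Oakley,
    Sazonov), the z-angle posture heuristic, reference classifiers, a
    trainable random-forest harness, and Webster rescoring.  Sleep endpoints
    (WASO, TST, sleep efficiency), per-subject confusion statistics, cohort
    aggregation, Bland-Altman agreement analysis and a sensitivity and
    specificity selection rule support analytical validation against
    polysomnography.  A synthetic cohort generator produces paired
    ground-truth hypnograms and raw acceleration so the full pipeline can be
    exercised without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
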