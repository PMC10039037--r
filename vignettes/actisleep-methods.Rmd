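---
title: "From wrist acceleration to sleep endpoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist acceleration to sleep endpoints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

`actisleep` implements the complete analytical chain used to validate
actigraphy sleep scoring against polysomnography (PSG): raw tri-axial
wrist acceleration is reduced to activity counts, counts (or the raw
signal) are classified into 30-s sleep/wake epochs by the classic
algorithm families, optional Webster rescoring is applied, and the
results are evaluated per subject with confusion statistics, sleep
endpoints (WASO, TST, SE) and Bland-Altman agreement, with a
sensitivity/specificity selection rule at the cohort level.  A synthetic
cohort generator supplies paired ground truth and raw signal so the
whole chain can be exercised and tested without clinical data.

This vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic evaluation does and does not
demonstrate.

## The epoch grid and data model

All labels live on a fixed grid of half-open windows `[t, t + 30 s)`
anchored at the PSG hypnogram start.  Half-open windows make boundary
sample assignment unambiguous; the epoch length must divide 60 s so the
1-min aggregation used by the older algorithms is exact.  Hypnogram
stages `N1/N2/N3/REM` binarize to *sleep* and `W` to *wake*; sleep is
the positive class everywhere.

Recordings with internal timestamp gaps are rejected rather than
imputed: the evaluation design assumes complete nights, and no
imputation rule could be validated here.  Trailing partial windows and
epochs are dropped, never padded, in all I/O paths; zero padding exists
only *inside* windowed classifiers, where a deterministic out-of-range
convention is required.

## Activity counts

The count stage emulates the legacy actigraph data-reduction chain.
Input at 40 Hz (produced by `downsample_mean()`, the 25-ms window-mean
reduction of the 85.7 Hz wrist signal) is processed per 30-s epoch and
per axis:

1. linear resampling to the filter's native 30 Hz;
2. band-pass filtering to the 0.29–1.63 Hz movement band (order-3
   Butterworth, the documented legacy analog band);
3. scaling by the legacy ADC conversion `(3/4096)/(2.6/256) × 237.5`
   (≈ 17.13 per g);
4. rectification, clipping at 2.13, dead-band below 0.068;
5. quantization to 8-bit resolution (steps of 2.13/128);
6. decimation to 10 Hz and accumulation over the epoch, with the
   per-axis epoch sum saturating at the 16-bit counter ceiling of
   32767, as legacy epoch files do.

Two numerical choices deserve emphasis.  First, the filter is applied
**per epoch** with steady-state initialization at the epoch's first
sample (previous inputs equal to that sample, previous outputs zero —
exact for a zero-DC-gain band-pass).  Counts are therefore a pure
function of each epoch's samples: constant (gravity-only) input yields
exactly zero counts, adding a constant offset to the signal changes
nothing, and permuting input epochs permutes count epochs identically.
A continuously streamed filter would violate these properties near
epoch boundaries.  Second, the 16-bit epoch-counter saturation is what
makes counts *exactly* constant beyond a ceiling amplitude; per-sample
clipping alone cannot achieve that, because samples near the zero
crossings of an oscillation keep scaling with amplitude below the clip
level.

Axis combination for the count classifiers defaults to the vector
magnitude `sqrt(cx² + cy² + cz²)` and is configurable (single axis and
the sixth-root-of-sum-of-squares combination used by count-normalizing
deep models are also provided).  Which combination fed the legacy
algorithms in historical datasets is generally unknowable; the run
manifest therefore always records the combination used.

## Classifier presets

Coefficients for the legacy algorithms ship in a versioned YAML file
(`inst/extdata/algorithm-presets.yaml`); every entry cites the original
publication and every value can be overridden at run time, keeping
disputed constants out of code and auditable.

* **Cole-Kripke** — weighted 1-min window, offsets −4…+2 with weights
  106, 54, 58, 76, 230, 74, 67, scale 0.001; sleep when the score is
  below 1.
* **Oakley** — symmetric five-minute kernel 0.04, 0.2, 1, 0.2, 0.04;
  sleep when the score is at or below the threshold.  The wake
  threshold is device-selectable (20/40/80); the default here is the
  medium setting 40, a documented open choice.
* **Sadeh** — `PS = 7.601 − 0.065·MW5 − 1.08·NAT − 0.056·SD6 −
  0.703·LG`, where MW5 is the mean count over the centered 11-min
  window, NAT counts window epochs in the 50–100 band, SD6 is the
  standard deviation of the current and five preceding minutes, and
  `LG = ln(counts + 1)`; sleep when `PS ≥ 0`.  The −4 threshold that
  circulates in secondary implementations is selectable.
* **Sazonov** — logistic regression on trailing-window maxima of 30-s
  counts: `score = 1.727 − 0.256·w1 − 0.154·w2 − 0.136·w3 − 0.140·w4 −
  0.176·w5`, sleep when `logistic(score) ≥ 0.5`.
* **simple_threshold** — the degenerate member of the window family
  (single weight 1 at offset 0): sleep when the current epoch's
  combined counts fall below 500.  It is the scale-robust baseline used
  in the end-to-end separability checks.

Models with a 1-min basis aggregate 30-s counts by pairwise summation
and broadcast each decision back to both constituent epochs, preserving
the algorithms' trained epoch basis while keeping the 30-s comparison
grid.  Window positions outside the recording read as zero counts — a
deterministic boundary convention matching common implementations.

The count classifiers are extremely sensitive to count *scale*: their
coefficients were fit to devices whose sleeping-wrist counts were
essentially zero.  On data whose sleep epochs carry counts of order
10² (as the synthetic cohort's sensor-noise floor does) they collapse
toward all-wake.  This is a property of the algorithms, not of the
implementation, and it is the reason count provenance is the chief
hazard when transporting these algorithms between datasets.  The unit
tests therefore verify the legacy classifiers against worked examples
at their native count scales, and the separability checks use the
scale-robust classifiers.

## The z-angle posture heuristic

The forearm elevation `atan(az / sqrt(ax² + ay²)) · 180/π` is computed
on per-axis 5-s rolling medians, averaged over consecutive 5-s blocks,
and successive absolute block changes are thresholded at 5°: maximal
runs of sub-threshold changes lasting at least 5 min become sleep,
everything else wake.  Block labels are resampled to 30-s epochs by
majority, with ties scored wake (conservative toward detecting
disturbance, consistent with the emphasis on specificity in algorithm
selection).  Block averaging is timestamp-based: at 85.7 Hz a 5-s block
is not a whole number of samples, and rounding it to one would drift
the block grid by tens of seconds across a night relative to the epoch
grid.

All four durations (median window, block, angle threshold, minimum
still duration) are exposed as parameters with the published defaults.
The angle is invariant to positive rescaling of the input, so the
heuristic needs no calibration of absolute sensitivity.

## Webster rescoring

Rescoring converts sleep scored near long wake runs to wake — never the
reverse — with the five classic rules: after ≥ 4/10/15 min of wake the
next 1/3/4 min of sleep are rescored (a–c), and sleep bouts ≤ 6/10 min
flanked on both sides by ≥ 10/20 min of wake become wake (d–e).  Rules
apply sequentially in the listed order, each on the output of the
previous; "after wake" rescores only the sleep run immediately
following a qualifying wake run.  Because the operator only removes
sleep, sensitivity can only fall and specificity only rise against any
fixed truth, for every rule subset — a property the test suite checks
exhaustively over random sequences.  Idempotence is *not* claimed
(cascades are possible); convergence within five applications is
checked instead.  The pipeline applies rescoring to the legacy count
algorithms only, which is where it was developed, though it is exposed
for any classifier.

## Endpoints, confusion statistics, and agreement

Sleep onset defaults to the first sleep epoch (a "first of k
consecutive epochs" alternative is provided, since onset has no
universal definition); offset is the last sleep epoch.  WASO is the
wake time between onset and offset, TST the total sleep time, SE the
percentage of the annotated period scored sleep.  With no sleep epochs,
TST and SE are 0 and WASO/onset are flagged undefined.

Per-subject confusion statistics use sleep as the positive class:
sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
F1 the harmonic mean of precision and sensitivity, accuracy
(TP+TN)/total, all as percentages.  Zero-denominator metrics propagate
as missing values with counts, never as silent zeros; the single
convention is F1 = 0 when there are no true positives but disagreement
exists, which is both the standard zero-division convention and the
value the all-wake reference row must take.  Cohort aggregation is
per-subject-then-average (unweighted mean and sample SD), which is what
makes a Bland-Altman analysis of the per-subject endpoints possible.

Bland-Altman agreement on an endpoint uses differences
`d = pred − truth`: mean error `ME = mean(d)`, `RMSE = sqrt(mean(d²))`,
Pearson correlation of the paired vectors, and limits of agreement
`ME ± 1.96 × SD(d)` with sample (n−1) SD.  RMSE is the root of the mean
squared difference — the only reading consistent with validation tables
in which RMSE greatly exceeds |ME|.  Algorithm selection retains those
with cohort-mean sensitivity ≥ 75% and specificity ≥ 45%.

## The synthetic cohort generator

The generator emulates the statistical structure the evaluation relies
on, not sleep physiology.  Defaults describe a 28-subject, single-night
(8-h) laboratory cohort with fragmented, disorder-heavy sleep:

| parameter | default | why |
|---|---|---|
| sleep bout mean | 50 min | consolidated sleep broken by awakenings |
| sleep bout floor | 5 min | scored sleep fragments below the posture heuristic's minimum still duration are not emulated, keeping generated truth separable by construction |
| wake bout mean | 5 min | brief nocturnal awakenings |
| wake movement | 0.5 g, 0.5–3 Hz | moderate wrist activity inside the count passband |
| posture shifts | every 2 min of wake | discrete orientation changes |
| elevation wander | 15–25° at 0.08–0.12 Hz | waking forearms change orientation continuously, and the wander must survive the 5-s median filter and remain visible at any base orientation |
| residual sleep movement | 5% of sleep epochs, 10-s bursts | disturbed sleepers |
| sensor noise | 0.01 g SD | white noise floor |
| sampling | 85.7 Hz | the wrist device's rate |

Bout lengths are geometric (memoryless) — the simplest model meeting
the evaluation's needs — with the sleep-bout floor implemented as a
shifted geometric that preserves the configured mean.  Sleep bouts keep
the last waking posture; wake orientation is parameterized by azimuth
and elevation, with the slow wander applied to the elevation angle
directly because a linear acceleration component is nearly invisible to
the z-angle when the base orientation is near vertical.  All randomness
flows from a single master seed with deterministic per-subject streams.

What the generated data does **not** contain: realistic sleep-stage
architecture, circadian modulation, non-wear, device calibration error,
scorer disagreement, or the heavy-tailed movement statistics of real
wrists.  Passing the end-to-end checks on synthetic nights therefore
demonstrates that the chain is implemented correctly and is separable
under its stated assumptions — it does not predict clinical accuracy on
real cohorts, where the published algorithms differ much more.

## Problem sizes and determinism

The test suite runs its end-to-end checks on one noiseless 8-h night
(separability of the posture heuristic and the count threshold, both
≥ 99% epoch accuracy), 2-h nights across 20 seeds and three residual
movement levels (monotone WASO response), 1,000 random label pairs
against a brute-force confusion oracle, and 500 random sequences times
all 32 rescoring rule subsets.  The analysis scripts run the full
28-subject, 8-h cohort.  Identical configuration and seed reproduce
byte-identical structured reports; the manifest records the preset
version, the axis combination and a content hash of the
analysis-defining configuration.
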