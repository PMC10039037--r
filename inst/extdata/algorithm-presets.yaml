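# Versioned coefficient presets for the sleep-wake classifiers.
# Every preset cites the publication its constants were taken from and can
# be overridden at run time; see load_presets().
version: 1

cole_kripke:
  source: >-
    Cole RJ, Kripke DF, Gruen W, Mullaney DJ, Gillin JC (1992).
    Automatic sleep/wake identification from wrist activity.
    Sleep 15(5):461-469. One-minute scoring mode, wrist counts.
  epoch_basis_s: 60
  scale: 0.001
  weights:
    "-4": 106
    "-3": 54
    "-2": 58
    "-1": 76
    "0": 230
    "1": 74
    "2": 67
  threshold: 1
  sleep_when: score_below

oakley:
  source: >-
    Oakley NR (1997). Validation with polysomnography of the Sleepwatch
    sleep/wake scoring algorithm used by the Actiwatch activity monitoring
    system. Mini-Mitter technical report. Symmetric five-epoch kernel;
    wake threshold selectable (20 low / 40 medium / 80 high); medium is
    the default here because the evaluated study does not state a setting.
  epoch_basis_s: 60
  scale: 1.0
  weights:
    "-2": 0.04
    "-1": 0.2
    "0": 1.0
    "1": 0.2
    "2": 0.04
  threshold: 40
  sleep_when: score_at_or_below

sadeh:
  source: >-
    Sadeh A, Sharkey KM, Carskadon MA (1994). Activity-based sleep-wake
    identification: an empirical test of methodological issues.
    Sleep 17(3):201-207. PS = 7.601 - 0.065 MW5 - 1.08 NAT - 0.056 SD6
    - 0.703 LG; sleep when PS >= 0. The alternative threshold -4 that
    circulates in secondary implementations is selectable.
  intercept: 7.601
  w_mean: -0.065
  w_nat: -1.08
  w_sd: -0.056
  w_log: -0.703
  nat_low: 50
  nat_high: 100
  window_epochs_each_side: 5
  sd_window_epochs: 6
  sleep_threshold: 0
  sleep_threshold_alternative: -4
  epoch_basis_s: 60

sazonov:
  source: >-
    Sazonov E, Sazonova N, Schuckers S, Neuman M, CHIME study group (2004).
    Activity-based sleep-wake identification in infants.
    Physiol Meas 25:1291-1304. Logistic regression on trailing-window
    maxima of 30-s epoch counts: score = 1.727 - 0.256 w1 - 0.154 w2
    - 0.136 w3 - 0.140 w4 - 0.176 w5; sleep when logistic(score) >= 0.5.
  intercept: 1.727
  window_weights:
    "1": -0.256
    "2": -0.154
    "3": -0.136
    "4": -0.140
    "5": -0.176
  probability_threshold: 0.5

simple_threshold:
  source: >-
    Package-native single-epoch threshold classifier: sleep when the
    current 30-s epoch's combined counts fall below the threshold. The
    degenerate member of the linear-window family (single weight 1 at
    offset 0); used for end-to-end separability checks.
  epoch_basis_s: 30
  scale: 1.0
  weights:
    "0": 1.0
  threshold: 500
  sleep_when: score_below

vanhees:
  source: >-
    van Hees VT et al. (2015). A novel, open access method to assess sleep
    duration using a wrist-worn accelerometer. PLoS ONE 10(11):e0142533.
    z-angle from 5-s rolling medians, 5-s block means, sustained (>= 5 min)
    absence of > 5 degree changes scored as sleep.
  median_window_s: 5
  angle_block_s: 5
  angle_change_threshold_deg: 5
  min_still_duration_min: 5

webster:
  source: >-
    Webster JB, Kripke DF, Messin S, Mullaney DJ, Wyborney G (1982).
    An activity-based sleep monitor system for ambulatory use.
    Sleep 5(4):389-399. Rescoring rules a-e, applied in order.
  rules:
    - {id: a, type: after_wake, min_wake_min: 4,  rescore_sleep_min: 1, enabled: true}
    - {id: b, type: after_wake, min_wake_min: 10, rescore_sleep_min: 3, enabled: true}
    - {id: c, type: after_wake, min_wake_min: 15, rescore_sleep_min: 4, enabled: true}
    - {id: d, type: surrounded, max_sleep_min: 6,  min_flank_wake_min: 10, enabled: true}
    - {id: e, type: surrounded, max_sleep_min: 10, min_flank_wake_min: 20, enabled: true}
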