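# winbci

Time-window effects in recurrent classification of eyes-open / eyes-closed
EEG, as a reproducible simulation-and-analysis pipeline in R.

## The problem

A minimal brain-computer interface for users with impaired motor function can
run on a deliberately simple command code: the user opens or closes their
eyes. Closing the eyes raises alpha-band (8-12 Hz) power over the occipital
electrodes O1/O2 — but that power fluctuates strongly within each state, and
short stretches of an eyes-closed recording look exactly like eyes-open
activity. A classifier fed single power samples is therefore unreliable,
while one that integrates a time window of the power sequence becomes
accurate at the cost of a slower response. The scientific question this
package operationalizes: **how does classification accuracy depend on the
window length, where does it stop improving, and what does the longer window
cost in detection latency?**

`winbci` implements the full chain on a synthetic 13-subject cohort (the
underlying human recordings of such studies are typically not deposited):

* `synth_config()` / `generate_cohort()` / `synth_stream()` — protocol-shaped
  14-channel EEG at 128 Hz with ground truth: lognormal occipital alpha with
  fast and slow envelope components and bounded eyes-closed alpha-dropout
  episodes, frontal eye-blink transients, 1/f + white noise, broadband
  artifact bursts.
* `remove_blinks()`, `bandpass_5_40()`, `rejection_mask()`,
  `preprocess_recording()` — regression-based blink denoising against an AFZ
  reference (mean of AF3/AF4), 5-40 Hz Butterworth filtering, and automatic
  artifact rejection at `mean + 3 sd` of the standardized channel sum.
* `morlet_power()` / `alpha_power_series()` — Morlet-wavelet alpha power at
  O1/O2, decimated to 16 Hz, with per-sample state labels.
* `make_sequences()` / `make_points()` / `split_train_val()` — sliding-window
  sequence datasets `{(P_O1, P_O2)_i, i = 1..n_w}` for the recurrent models
  and pointwise `(P_O1, P_O2)` rows for the classical roster.
* `train_lstm()` (compiled forward/BPTT core, verifiable against the plain-R
  gate recurrence `lstm_cell_step()`), `train_rnn()` (tap-delay recurrent
  baseline), `train_pointwise()` (trees with split budgets, LDA/QDA, SVMs at
  the stated kernel scales, k-NN with four distances).
* `window_study()` / `pointwise_study()` — repeated stratified 75/25
  split-train-validate cycles per subject; accuracy, sensitivity,
  specificity, MCC (eyes-closed positive); subject-level aggregation with
  the n-1 convention; Friedman test across windows plus pairwise Wilcoxon
  signed-rank post-hocs.
* `stream_classify()` — online simulation: classify the trailing window at
  every power sample (mixed-state windows included) and measure per-transition
  detection delays against a hold-time criterion.
* `run_all()` / `run_stage()` — the whole pipeline as re-runnable stages with
  a hashed manifest; `inst/cli/winbci.R` is a thin shell entry point.

## Worked example

```r
library(winbci)

cfg  <- load_config()                  # all pipeline defaults
scfg <- synth_config(seed = 1)         # 13 subjects, 10 trials each

ps <- lapply(seq_len(scfg$n_subjects), function(i) {
  sub <- generate_subject(scfg, i)
  pp  <- preprocess_recording(sub$recording, cfg)
  alpha_power_series(pp$recording, pp$mask, cfg)
})

ws <- window_study(ps, cfg$study$windows_s, cfg)
print(ws)
```

```
<window_study>
 window_s acc_mean  acc_sd sen_mean  sen_sd spe_mean  spe_sd mcc_mean mcc_sd
        1   0.7657 0.06024   0.7705 0.07143   0.7610 0.07034   0.5357 0.1216
        2   0.7927 0.06786   0.7896 0.09730   0.7956 0.07182   0.5918 0.1350
        4   0.8320 0.05617   0.8183 0.06810   0.8454 0.06034   0.6682 0.1115
        7   0.8899 0.05302   0.8874 0.07977   0.8927 0.04708   0.7845 0.1033
       10   0.9049 0.06455   0.8983 0.08893   0.9118 0.05456   0.8145 0.1252
Friedman chi-square = 46.215, p = 2.22e-09
```

Mean LSTM accuracy climbs from 0.77 at a 1 s window to 0.89 at 7 s and then
flattens: the pairwise Wilcoxon matrix (`ws$wilcoxon_p`) gives p = 0.094
between the 7 s and 10 s windows (no significant gain from the longer
window) but p < 0.001 between 1 s and 7 s. The classical pointwise roster on
the same cohort (`pointwise_study(ps, cfg)`) tops out at 0.77 (a coarse
decision tree), ~12 percentage points below the plateau-window LSTM — single
power samples simply cannot distinguish an eyes-closed alpha dropout from
genuine eyes-open activity. The streaming simulator shows the price of the
window: eyes-closed-to-eyes-open transitions are detected after roughly the
window length, so a 7 s window buys its accuracy with seconds of latency.

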