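---
title: "Time windows and recurrent classification of eyes-open/eyes-closed EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time windows and recurrent classification of eyes-open/eyes-closed EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A brain-computer interface built on a low-cost wireless EEG headset can use a
deliberately simple command code — the user opens or closes their eyes — because
closing the eyes reliably raises alpha-band (8-12 Hz) power over the occipital
cortex (electrodes O1 and O2). The difficulty is that alpha power is not a
clean step function of the eye state: it fluctuates strongly within each state,
and short stretches of an eyes-closed recording can look exactly like eyes-open
activity. A classifier fed single power samples therefore performs poorly,
while a classifier that integrates a longer window performs better but responds
more slowly. `winbci` implements the full pipeline needed to quantify this
accuracy-latency trade-off: synthetic cohort generation, blink denoising,
band-pass filtering, artifact rejection, Morlet alpha-power extraction,
sliding-window dataset construction, an LSTM sequence classifier with classical
baselines, and the repeated-evaluation statistics that compare window lengths.

## The synthetic cohort

The human recordings this kind of study is based on are not publicly
deposited, so the package ships a generative model whose purpose is to possess
exactly the statistical structure the analysis exploits, with ground truth for
every nuisance component:

* **Occipital alpha rhythm.** O1/O2 carry a sinusoid near 10 Hz (per-subject
  frequency jitter of +-0.5 Hz) whose amplitude envelope is lognormal:
  `A(t) = exp(mu_state + sigma_f u_f(t) + sigma_s u_s(t))`, with
  Ornstein-Uhlenbeck processes `u_f` (fast, timescale ~1 s, per-subject
  jittered) and `u_s` (slow, ~30 s). The eyes-closed log-mean `mu_EC` exceeds
  `mu_EO` (defaults: median 10 uV vs 4 uV), so the states separate on average
  while single samples overlap heavily.
* **Why two timescales?** The fast component is what a longer window can
  average away — it creates the accuracy-vs-window-length curve. The slow
  component is a state-independent excitability drift that no window of a few
  seconds can remove — it caps the achievable accuracy. With a single
  timescale the accuracy curve keeps rising to the longest window.
* **Alpha-dropout episodes.** During eyes-closed time the envelope
  intermittently falls to its eyes-open level for a bounded stretch
  (default ~3/min, 1-4 s, smooth shoulders) while the label stays
  eyes-closed — closed-eye alpha genuinely waxes and wanes this way, and it
  is the reason single power samples cannot be classified reliably. These
  episodes are the plateau mechanism: any window a few times longer than the
  longest episode still contains unambiguous eyes-closed evidence, so
  accuracy stops improving once the window passes that scale, while short
  windows that fit inside an episode are systematically misled.
* **Blinks.** Smooth biphasic difference-of-Gaussians pulses (~350 ms, peak
  ~80 uV) mixed onto the frontal channels (AF3/AF4 weight 1.0, F7/F8 0.6),
  drawn as a Poisson process (~15/min) only while the eyes are open. Their
  spectrum is concentrated below ~5 Hz, where the regression-based denoiser
  expects them.
* **Noise and artifacts.** Independent 1/f plus white noise on every channel
  (4 + 2 uV RMS), and rare broadband bursts (~0.5/min, 150 uV, 0.5 s) hitting
  all channels simultaneously, which the z-threshold rejection should flag.
* **Protocol.** 20 s eyes open, 10 s rest (black screen), 20 s eyes closed,
  repeated; 13 subjects by default. Rest segments carry eyes-open-like alpha
  but are excluded from classification. The number of trials per subject is
  not part of the protocol definition we follow; the default of 10 per state
  gives per-subject datasets large enough for stable training.

What the generator does **not** model: volume conduction and realistic
topographies, non-alpha rhythms, electrode drift and motion artifacts beyond
broadband bursts, or fatigue effects. Passing tests on this cohort therefore
show that the pipeline recovers the intended structure when it is present, not
that the classifier numbers transfer to any particular human dataset.

## Pre-processing

1. **Blink denoising.** The reference `AFZ` is the mean of AF3 and AF4 (the
   headset has no true frontal-midline electrode). Its 1-7 Hz component
   (5th-order Butterworth) is the regression signal; the squared, standardized
   derivative, smoothed with a 125 ms moving average, is the detection signal.
   Maximal runs above `k = 5` times its median (padded by 0.1 s, merged)
   are blink intervals. Inside the intervals only, each channel has
   `w_ch * regr` subtracted, with `w_ch = mean(|x_ch|) / mean(|AFZ|)`
   estimating the share of the reference signal present in the channel.
   The weight is estimated **on the blink intervals** by default: estimated
   over the whole recording, `w_ch` is biased upward by the ratio of the
   channel noise floor to the AFZ noise floor (AFZ averages two channels, so
   its floor is ~sqrt(2) smaller), which measurably degrades the correction.
   A `weight_scope = "recording"` option restores the whole-recording
   convention.
2. **Band-pass.** 5-40 Hz Butterworth (order 5), zero-phase (forward-backward)
   offline; a causal single-pass mode exists for streaming use where zero-phase
   filtering would be acausal.
3. **Artifact rejection.** Every channel is standardized with the population
   (1/N) convention, summed and divided by `sqrt(c)`; samples where this
   exceeds `mean + 3 sd` (population) are rejected, dilated by 10 ms. The
   threshold adapts to the recording by construction; on clean Gaussian data
   it flags the upper ~0.13% tail. The rule is deliberately one-sided: the
   combined standardized sum is driven upward by coherent multi-channel
   artifacts.

Masked samples (rejected, wavelet edges, unannotated time) are **excluded from
dataset construction**: sequence windows are built over maximal runs of
unmasked same-state power samples, splicing over short gaps. The alternative —
vetoing every window that contains any masked sample — interacts badly with a
3-sigma rule, which flags a scattering of samples on even the cleanest data:
almost no 7-10 s window would survive, and the long-window study the method
exists for would be impossible. Splicing keeps the label purity guarantee
(windows never cross state boundaries) at the cost of rare, small
discontinuities inside a window.

## Features and datasets

Alpha power is the squared magnitude of a complex Morlet transform, averaged
over 8-12 Hz in 0.5 Hz steps with 7 cycles (a common choice balancing time and
frequency resolution; both are config keys). The power series is decimated by
8 (to 16 Hz) — power envelopes at these frequencies carry no usable structure
above a few hertz, and sequence lengths stay tractable. Window lengths are
counted on the decimated series: a 7 s window is a 112-step sequence.

The sequence dataset anchors windows at each segment's last sample and slides
backwards; the hop between window ends is 1 decimated sample for
`make_sequences()` itself, but the study configuration uses a hop of 16
(1 s): with ten 20 s trials per state and five window lengths, denser
overlap multiplies training cost without changing the estimated accuracies
noticeably. The pointwise dataset is simply every unmasked EO/EC power sample,
with no further transformation. Splits are random and class-stratified, 75/25
by default; stratification is our choice (the convention is otherwise
unspecified) and is documented here.

## Classifiers

The LSTM follows the standard gate equations: forget, input and candidate
transforms act on `[h_{t-1}, x_t]`; `c_t = f_t c_{t-1} + i_t c~_t`. The
output gate `o_t = sigma(W_o [h_{t-1}, x_t] + b_o)`, `h_t = o_t tanh(c_t)` is
the standard completion of the cell. One layer of eight cells feeds a dense
layer and a softmax over the two states; stacking layers feeds each layer's
hidden sequence to the next. Training is Adam on cross-entropy (lr 0.01,
batch 32, 60 epochs, Glorot initialization, forget-gate bias 1), fully
deterministic under a seed. The forward pass and backpropagation-through-time
are compiled (RcppArmadillo) for speed; the forward pass is independently
testable against a plain-R scalar recurrence of the gate equations
(`lstm_cell_step()`), and the test suite holds them to 1e-10 agreement.

The tap-delay RNN is a single recurrent layer `h_t = tanh(W_x x_t +
W_h h_{t-d} + b)` with the feedback delayed by `round(delay_s * fs_power)`
steps and the same head; eight units, matching the LSTM so that the
comparison isolates the cell type rather than capacity.

The classical roster covers the standard options at fixed settings: decision
trees grown fully and pruned back to at most 100/20/4 splits; linear and
quadratic discriminant analysis; SVMs with linear, quadratic, cubic and
Gaussian kernels at kernel scales sqrt(P)/4, sqrt(P), 4 sqrt(P) (P = 2,
`gamma = 1/scale^2`); k-NN with k = 1/10/100 and euclidean, cubic
(Minkowski-3), squared-inverse-distance-weighted and cosine distances.
Trees, DA and SVMs are backed by rpart, MASS and e1071; the k-NN variants are
computed directly because the stated distance options are not all available
in one library implementation. SVM features are standardized internally —
the kernel scales above are only meaningful on standardized predictors, and
raw uV^2 powers make the polynomial kernels numerically ill-posed; all other
families see raw power values ("no additional transformations").

## Evaluation

Eyes-closed is the positive class throughout. Accuracy, sensitivity,
specificity and the Matthews correlation coefficient come from the validation
confusion matrix; undefined values (empty class, zero MCC denominator) are
reported as `NA`, never as 0. Each subject-window pair is evaluated over J
independent split/train/validate cycles; the per-subject means are averaged
over subjects, and the spread is the sample (n-1) standard deviation of the
per-subject means. The default J is 5 — the cohort-level conclusions are
driven by the 13 subjects, and larger J mainly polishes the per-subject
means; J = 20 is one config key away.

Windows are compared with the Friedman test on the subjects-by-windows
accuracy matrix (average-rank ties, chi-square reference with k-1 degrees of
freedom) and post-hoc two-sided Wilcoxon signed-rank tests per window pair
(zero differences dropped by default, with a Pratt option; exact null for up
to 25 informative pairs, normal approximation beyond; no multiplicity
correction by default, Holm optional). These conventions are stated here
because they are otherwise easy to leave ambiguous.

The streaming simulator classifies, at every power sample, the window ending
there — mixed-state windows included — and measures per true transition the
delay until the prediction switches to the new state and holds for
`hold_s = 1` s. The hold time exists because instantaneous classifiers
flicker; without it a single lucky sample would count as a detection. A
detected delay can therefore not exceed the window length plus the hold time
by construction, and longer windows pay for their accuracy with longer
eyes-closed-to-eyes-open delays.

## Numerical and design notes

* Population (1/N) standard deviations inside the rejection rule; sample
  (n-1) only for subject-level aggregation.
* The channel sum divides by `sqrt(c)` rather than `c`, preserving unit
  variance for independent channels; this is the conventional form of the
  rule and the tests pin it down algebraically.
* Argmax ties in prediction resolve to eyes-open, the negative class.
* The wavelet transform flags samples within half a wavelet support (3 sigma
  at the lowest frequency) of either recording edge; they are treated as
  masked.
* Degenerate inputs fail loudly: constant channels cannot be standardized,
  constant detection signals cannot be thresholded, single-class datasets
  cannot be trained on, `k` larger than the training set is an error.
* Problem sizes used by the shipped study: 13 subjects, 10 trials per state,
  windows {1, 2, 4, 7, 10} s, J = 5, hop 16 decimated samples, 60 training
  epochs. These sizes are the package's default study definition; every one
  of them is a config key.

## Known limitations

* The generator's plateau location is set by its envelope timescales; it
  emulates the qualitative phenomenon, not any specific subject population.
* Sequence splits are random over heavily overlapping windows, so train and
  validation windows can share underlying samples; per-subject accuracies
  are therefore optimistic relative to a fully held-out-trial design.
* The streaming mode trains on protocol data and tests on a separately
  generated stream from the same subject model; cross-subject transfer is out
  of scope.
* Friedman p-values use the chi-square approximation; for very small cohorts
  it is conservative, which the acceptance tests quantify against a
  permutation null.
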