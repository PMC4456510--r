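---
title: "Methods: simulating and analyzing Drosophila virilis duets"
author: "virduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing Drosophila virilis duets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virduet)
```

## The scientific problem

During courtship, *Drosophila virilis* males and females sing to each other
with wing vibration, producing trains of brief acoustic pulses. The two
sexes coordinate: the female tends to answer a male bout at a
characteristic latency after its onset, and the male starts his next bout
shortly after her last pulse (antiphonal duetting). Quantifying this
requires (i) segmenting single-microphone recordings into male and female
pulses, (ii) summarizing song structure (inter-pulse intervals, bouts,
rates, overlaps), (iii) measuring response-latency distributions against
shuffled nulls, and (iv) relating song production and timing to sensory
channels and to the male's contact behaviors with regression models.

`virduet` implements that whole chain, together with a seeded simulator
that produces recordings with known ground truth, so every stage can be
validated quantitatively without access to recordings.

## The simulator

`simulate_duet()` generates a duet as alternating exchanges:

1. a male bout with a pulse count drawn from a rounded Gaussian
   (6.9 ± 1.2, floored at 4) and within-bout inter-pulse intervals (IPIs)
   from a Gaussian (21.2 ± 1.9 ms) truncated at the 25 ms bout-definition
   threshold;
2. a female train starting at a log-normal latency after the male bout
   onset (mode 409 ms), with an overdispersed negative-binomial pulse
   count (7.2 ± 6.2, floored at 1) and truncated-Gaussian IPIs
   (55.2 ± 26.3 ms, below the 100 ms train threshold);
3. the next male bout at a log-normal latency after the last female pulse
   (mode 110 ms). With probability 0.1 an exponential silent gap
   (mean 4 s) is inserted, mimicking the long silent stretches of real
   courtship.

With a small per-exchange probability (default 0.02) one female pulse is
placed inside the male bout, producing the rare song overlaps seen in real
pairs. Pulses are Gabor atoms (sinusoid under a Gaussian envelope) at
configurable carriers — defaults 400 Hz (male) and 250 Hz (female), chosen
to be well separated inside the 100–900 Hz analysis band; published
spectra show male pulses peaking above female pulses but print no carrier
values, so these defaults are explicitly not literature values. Gaussian
background noise (sd 0.02 against unit pulse amplitude) completes the
trace.

Design notes on the stochastic choices:

* **Truncation at the bout thresholds.** The published IPI summaries
  describe pulses already grouped into bouts by the 25/100 ms rules;
  drawing untruncated IPIs would split simulated bouts at random and bias
  pulses-per-bout low. Truncation shifts the realized mean IPI by well
  under 0.2 ms.
* **Log-normal latencies.** Observed response-time distributions are
  unimodal and right-skewed. The log-normal is parameterized by its mode
  (the quantity reported for the real distributions) and a log-scale
  spread. Spread defaults (0.25 female, 0.30 male) were fixed once, by a
  precision analysis of the kernel-density peak estimator: at the sample
  sizes the package's validation runs use (roughly 2,000–3,000 pooled
  latencies) the peak of a log-normal with these spreads is estimable to
  ~10–15 ms, comfortably inside the ±25 ms equivalence band used for
  validation, while the distributions remain realistically broad.

`simulate_behavior_tracks()` adds frame-level (60 fps) annotation tracks
for three male contact behaviors. The male's courtship forms a behavioral
sequence — he vibrates his tarsi on the female abdomen and licks her while
she sings, then sings himself — so each behavior receives two kinds of
episodes: one locked to each female train (lag 0 by default, jitter under
one frame), and one mirroring each upcoming male bout, shifted earlier by
a configurable lead (defaults: 200 ms tarsal vibration, 50 ms licking).
The mirrored episode is duration-matched to the bout, which makes the
behavior-at-lead feature an exact time-shifted copy of the song response;
this is what lets a lagged regression recover the lead cleanly (see the
history-GLM section). Tarsal-pause episodes fill the gaps between
vibration episodes. Earlier designs with fixed-duration episodes anchored
to bout onsets or centers were rejected: all lags inside the
episode–bout cross-correlation trapezoid are then collinear, and the
fitted filter's argmax wanders over several frames.

`simulate_playback_stimulus()` reproduces the playback protocol: a bout
low-passed at 300 Hz (Butterworth), repeated 6 times at 1.2-s onsets,
with groups delivered every 30 s over 10 min.

What the simulator does *not* emulate: amplitude variation with distance
and orientation, room acoustics, non-stationary noise, male secondary song
modes, and annotation errors. Passing tests therefore demonstrate that the
analysis code recovers known structure under its own assumptions, not that
segmentation would reach the same accuracy on arbitrary real recordings.

## The segmenter

`wavelet_transform()` computes the magnitude of a continuous wavelet
transform with a frequency B-spline (fbsp) mother wavelet at `n_freqs`
(default 33) log-spaced frequencies spanning 100–900 Hz, one coefficient
column per audio sample. The fbsp daughter at analysis frequency
*f₀* is applied directly in the frequency domain as a B-spline window of
order *m* (default 2) centered on *f₀* with relative bandwidth *fb*. The
bandwidth default is 0.3: the window then spans about *f₀*/6 in frequency
and ~33 ms in time at 400 Hz, long enough that the ~9 ms silent gaps
between male pulses stay above the noise cutoff and a bout forms one
connected non-noise segment — which the labeling rule cascade presupposes.
All three fbsp parameters are exposed in `segmenter_config()`.

Each song class — male pulse (M), female pulse (F), overlapping pulse (O),
noise (N) — is a `song_template`: the mean wavelet spectrum of its
training examples, a principal-component basis (default 8 axes), and a
1-D Gaussian mixture (default 3 components, EM via mclust) along each
axis. `classify()` projects each time point into each template's frame,
sums per-axis log mixture densities into a log-likelihood, and converts
the four log-likelihoods to posteriors by softmax — the uniform-prior
posterior, computed stably in the log domain. The noise template is refit
per recording from time points whose broadband magnitude falls below a
low quantile (default 0.2) of that recording, absorbing differences in
noise floor between data sets.

`label_segments()` applies the published rule cascade with its published
constants: time points with p(N) > 1/2 are zeroed; a connected non-noise
run is M if its mean p(M)+p(O) exceeds its mean p(F) and it lasts at least
100 ms; remaining runs of at least 15 ms are F; inside M segments, a
pointwise run of p(F)+p(O) > 0.8 lasting at least 15 ms is an embedded
female pulse. Two readings were genuinely open: the M-vs-F comparison is
written pointwise but applied to whole segments — we compare the mean
posterior over the segment (deterministic and robust); the embedded-female
rule says "over a region", so it is applied pointwise as a run-length
condition.

Pulse localization is not specified by the original description, so the
package defines it: within each labeled segment, pulses are local maxima
of the rectified trace smoothed over 2 ms, above an adaptive threshold
(2× the segment's median envelope), with a minimum peak separation of
10 ms (M) / 15 ms (F). `score_segmentation()` matches predicted to true
pulses greedily one-to-one within ±10 ms (both defaults config-exposed)
and reports sensitivity, positive predictive value and their harmonic
mean, per sex.

The end-to-end pipeline (`segment_audio()`) decimates input audio to
2.5 kHz before analysis: the analysis band ends at 900 Hz, so a 1250 Hz
Nyquist preserves it while cutting the transform and classification cost
fourfold. On simulated wild-type recordings the pipeline reaches pulse
f-scores above 0.98 for both sexes at ±10 ms tolerance.

The original workflow included a manual correction pass by visual
inspection; that is out of scope here, and reproducible corrections can
instead be applied to the pulse CSVs between stages.

## Song statistics

Bout assembly and the summary statistics follow the published definitions
exactly: male bouts are runs of ≥4 pulses with IPIs < 25 ms; female trains
are runs with IPIs < 100 ms; per-individual median IPIs use 100 ms (M) /
500 ms (F) interval thresholds; rates are counts per total courtship time
(first to last pulse of either sex) with rates forced to 0 below 20 s of
cumulative song; overlap is the percentage of male bouts containing a
female pulse. Two definitions the source leaves open are documented
choices here: "cumulative song" for the 20-s rule is the summed span of
that sex's bouts, and the per-record normalization of the pre-copulation
female song profile is max-normalization (sum-normalization available via
a flag). The square-root transform of female pulse rates is available for
presentation only; statistics always run on raw rates.

## Response timing

`response_times()` measures, within a 1.5-s window: female response times
(male bout onset → next female pulse, overlaps included), male response
times (male bout onset → a chosen reference pulse of the preceding female
train: first, second, penultimate or last), and the playback variant
(bout offset → next female pulse, overlaps ignored). `shuffle_null()`
permutes female IPIs or male inter-bout intervals within a recording and
rebuilds event times by cumulative sum — preserving each singer's interval
statistics while destroying coordination. `summarize_distribution()` bins
latencies at 50 ms over [0, 1.5] s, attaches 95% percentile confidence
bands from 500 bootstrap resamples, and reports the distribution peak as
the argmax of a Gaussian KDE (bandwidth 25 ms, config-exposed) — more
robust to bin placement than a histogram argmax. Kolmogorov–Smirnov
comparisons use the standard two-sample test; Kullback–Leibler divergences
are computed on the shared bin grid with additive smoothing ε = 1e−6
(reported in nats alongside ε, since KL without smoothing is undefined on
empty bins).

## Rate GLMs

`fit_rate_glm()` links per-pair song rates to ±1-coded predictors
(sensory channel present/absent, or mating state × courtship success)
through a Poisson GLM with log link. "z-scoring the data" before fitting
is ambiguous in the source — z-scoring a count response would break the
Poisson support — so the package standardizes predictor columns only and
leaves the response on its natural scale. When counts and durations are
available the model is a count GLM with a log-duration offset (the exact
Poisson formulation); otherwise a quasi-Poisson fit on the rates.
`bootstrap_coefficients()` resamples pairs with replacement for bootstrap
standard errors.

## History-filter GLMs

`build_history_design()` turns 60 fps binary tracks into a lagged design:
for each frame, the previous 64 frames (~1 s) of each behavior.
`fit_sparse_logistic()` fits a logistic GLM with an elastic-net penalty,
bias unpenalized, penalty strength chosen by seeded cross-validation when
not supplied. The sparsity prior exists because annotated behaviors are
strongly auto- and cross-correlated, which inflates non-predictive
weights; pure L1 turned out to allocate weight unstably among collinear
neighboring lags (the argmax of the filter jumped between the edges of
the predictive window), so the default mixing keeps a small ridge
component (α = 0.95) whose grouping effect stabilizes the filter shape;
α is exposed, with α = 1 giving pure lasso and α = 0 pure ridge.

Performance is the relative deviance reduction — one minus the ratio of
held-out binomial deviance to that of a bias-only model — averaged over
80/20 random subsampling splits (default 20). `bootstrap_filters()`
repeats the fit on random 75% subsets, subsampling contiguous one-second
frame blocks rather than single frames to respect autocorrelation.
`filter_peak_lag()` reports the lag of the maximum weight in ms
(ties break toward the smaller lag, flagged); `stepwise_two_variable()`
ranks single-behavior models and measures the gain from adding each
remaining behavior to the best one.

## Validation scale and numerical choices

The package's validation runs (tests and the acceptance script) use the
study's sizes where stated — 13 two-minute courtships for song structure,
89 pairings for the overlap statistic, pooled response-time sets exceeding
1,000 latencies, ten 10-minute annotated courtships for the history
GLMs — and one-minute recordings per overlap pairing, the package's own
choice of problem size. Numerical safeguards: mixture variances are
floored (default 1e−12) with a warning on degenerate axes; posteriors are
computed by shifted softmax; empty or too-short inputs return flagged
absent values rather than failing; all randomness flows through explicit
integer seeds, and fixed seeds give bit-identical outputs.

## Known limitations

* Carrier frequencies, fbsp parameters, PCA dimensionality and GMM sizes
  have no published values; defaults are documented choices, exposed in
  configuration.
* The simulator's strict alternation cannot produce extended
  counter-singing or male–male interactions.
* KL divergences and GLM coefficient magnitudes from real recordings are
  data-dependent and are not reproduction targets of the synthetic
  validation.
* Female "bouts" built from single pulses have zero span; rate rules and
  rasterization treat them accordingly.
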