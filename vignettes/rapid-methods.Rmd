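---
title: "A patient-adaptive surprise index for continuous paediatric vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A patient-adaptive surprise index for continuous paediatric vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidindex)
```

## The problem

Hospitalised children deteriorate along a spectrum, and intermittent bedside
observations — even when aggregated into a Paediatric Early Warning (PEW)
score — sample that spectrum only every one to four hours. Wireless sensors
(an ECG patch for heart and respiratory rate, a wrist pulse oximeter for
SpO2 and pulse rate) deliver a per-minute multichannel stream instead, but
the stream is noisy, frequently interrupted, and has no universal "normal
range": a healthy neonate's vitals would alarm any chart written for a
twelve-year-old.

`rapidindex` implements a per-minute *surprise index* for such streams. The
premise is that a patient is summarised not by instantaneous values but by
the joint dynamics of heart rate, respiratory rate and SpO2 over a short
window. Patients whose dynamics resemble each other form *phenotypes*; a
patient whose current dynamics drift away from every phenotype is surprising
and may be deteriorating, whatever their absolute vital signs are.

## The pipeline

Scoring one minute of one patient runs through six stages, each an exported
function:

1. **Validity filtering** (`filter_session`). Broad clinical-range filters
   remove technical noise: heart and pulse rate outside 20–300 beats/min,
   respiratory rate outside 5–200 breaths/min, SpO2 below 30%. Bounds are
   read exclusively — a value exactly at a bound is kept. Quality is
   reported per sensor as captured and valid fractions of the intended
   monitoring time.
2. **Windowing** (`make_windows`). Sliding 15-minute windows at 1-minute
   stride over the three channels, standardized by channel statistics
   frozen at training time. Gaps up to 5 minutes inside a window are
   carried forward; windows less than 80% observed are unusable. Fifteen
   minutes is short enough to track change yet long enough to identify a
   low-order model; it also matches the imputation horizon.
3. **Signal conditioning** (`svd_condition`). The window matrix is replaced
   by its best rank-2 approximation. The discarded third singular
   direction carries the smallest-variance, highest-frequency content —
   sensor jitter rather than physiology. The discarded energy
   (1 − retained squared singular values / total) is recorded.
4. **Dynamics modelling** (`fit_var`). A vector autoregression of order 2
   (`x_t = c + A1 x_(t-1) + A2 x_(t-2) + e_t`) is fit by least squares,
   with the residual covariance from the one-step residuals. Because the
   conditioned window has rank 2, the regressor matrix is rank-deficient
   by construction and the documented ridge path (jitter `1e-6` times the
   mean normal-equation diagonal) provides the deterministic minimum-norm
   solution.
5. **Dissimilarity and projection** (`model_dissimilarity`,
   `train_neuroscale`). Two fitted models are compared by the symmetrised
   Kullback–Leibler divergence of their Gaussian one-step predictive
   distributions, averaged over a shared set of reference windows — the
   deviation between what each model *expects* the same data to do next.
   A radial-basis-function network (Gaussian basis, up to 50 k-means
   centres, width = median inter-centre distance, plus a bias) maps model
   descriptors — coefficients, intercept and the Cholesky factor of the
   residual covariance — to two dimensions, trained to preserve the
   dissimilarities by minimising the Sammon-type stress
   `sum((d_ij − ||y_i − y_j||)^2)`. Training starts from classical metric
   scaling and descends by gradient steps on the output weights with a
   backtracking step size, so the stress trace is monotone; with as many
   centres as points the network can realise the unconstrained optimum,
   which the tests verify against a brute-force MDS oracle.
6. **Index and alarms** (`compute_rapid_index`, `generate_alerts`). At a
   projected point the map's Jacobian `J` gives the local metric
   `G = J Jᵀ` and magnification `sqrt(det G)` — the local area scaling of
   the visualisation space, our operational reading of its local
   curvature. The index is the absolute robust z-score (median/MAD over
   training) of the log-magnification, plus the floored robust z-score of
   the negative log kernel density of the training projections at the
   point. A maximal run of minutes at or above the calibrated threshold is
   one alarm.

The first index value appears at minute 5, using an expanding window until
the full 15 minutes are available.

### Why the index has two components, and why the first is two-sided

Magnification alone is not monotone in novelty: a Gaussian RBF map's
Jacobian decays to zero far from the training support, so an extremely
deranged patient would project onto the network bias with *low*
magnification. Both directions of departure from the training
magnification distribution are therefore surprising — stretching marks
sparse regions inside the support, collapse marks points beyond it — which
is why the magnification z-score enters as an absolute value. The density
term adds a complementary, monotone measure of how unpopulated the
projected neighbourhood is. Both are standardized against the training
distribution and non-negative, and their sum is the index; the density
weight is configurable (`density_weight`, default 1, 0 disables it).

### Threshold calibration

The alarm threshold is the nearest-rank 95th percentile of pooled
per-minute index values. Patients used to build the map are structurally
unsurprising to it, so calibrating on them would understate the index of
every future patient. `train_rapid_model` therefore holds out a fraction
(default 0.3) of the eligible training sessions from map-building and
calibrates the threshold on their per-minute index — the deployed
statistic, measured out of sample. With a 95th-percentile threshold the
expected alarm load on stable patients is about 5% of scored minutes.

### Phenotypes and imputation

Training projections are clustered by k-means, with the cluster count
chosen by the best average silhouette width over 2–8. Each phenotype keeps
pooled channel statistics (mean, SD, lag-1 autocorrelation). When one
sensor goes quiet for at most 15 minutes, the missing channel is continued
along the conditional mean path of the patient's current phenotype AR(1)
model, `m + phi^k (last − m)`; the path is deterministic so that scoring
is exactly reproducible. Longer gaps make the index unavailable rather
than imputed; before any phenotype is assigned the last observation is
carried forward instead.

## The synthetic generator

No patient data accompanies the method, so `generate_session` and
`generate_cohort` produce the study conditions the package is exercised
under:

* per-minute cadence with two sensors (chest ECG: HR and RR; pulse
  oximeter: SpO2 and PR);
* age-dependent baselines interpolated smoothly over 0–216 months
  (maturation is gradual; piecewise-constant bands would make an infant
  categorically unlike a toddler, which is an artifact, not physiology);
* a shared latent AR(1) "stress" factor loading HR and RR positively and
  SpO2 negatively — the cross-channel interaction structure phenotype
  clustering assumes — plus per-channel AR(1) noise and a circadian term;
* i.i.d. per-minute per-sensor dropout, defaults 0.07 (chest ECG) and
  0.45 (pulse oximeter), chosen to reproduce capture fractions around 93%
  and 55% of intended monitoring time;
* artifact minutes replaced by values outside the clinical validity
  ranges, so filtering recovers the injected artifact count exactly;
* deterioration as a linear ramp from an onset to an event, parametrised
  by the *total excursion at the event* (defaults HR +40, RR +20,
  SpO2 −8): a child at a significant deterioration is severely deranged
  whether the decline took four hours or two days, so severity at the
  event, not the hourly rate, is held invariant when sessions are scaled
  down. Cohort defaults draw the onset-to-event gap around a 47-hour
  median over 96-hour sessions.

Cohort ages are stratified uniform draws over 1–192 months (one draw per
equal-width bin, then shuffled), emulating the representativeness of a
deliberately assembled training sample; small i.i.d. cohorts would
otherwise regularly miss entire age ranges and make every infant look
novel.

What the generator does **not** emulate: bursty (autocorrelated) dropout,
movement-artifact structure, therapy effects (oxygen, ventilation,
vaso-active drugs), arrhythmias, and any claim of clinical fidelity in the
baselines. Passing tests therefore demonstrate the machinery's
correctness and its behaviour under plausible statistical structure, not
clinical performance.

## Evaluation statistics

The case-control machinery mirrors standard diagnostic-accuracy practice
for early-warning evaluation: a case session counts as detected if any
alarm falls within the detection window (24 h or 72 h) *before* its event
— warning times are reported as detection-to-event, which anchors the
window there; a control session with any alarm is a false positive.
Sensitivity and specificity carry exact Clopper–Pearson 95% intervals.
PPV and NPV are computed at a fixed assumed prevalence (default 5.6%) as
`PPV = se·π / (se·π + (1−sp)(1−π))` and
`NPV = sp(1−π) / ((1−se)π + sp(1−π))`, with logit-transformed intervals
after Mercaldo, Lau and Zhou. Paired methods are compared by McNemar's
test — exact two-sided binomial below 25 discordant pairs, the
continuity-corrected chi-square otherwise — and warning-time summaries use
inclusive linear interpolation (type-7) quartiles.

## Numerical choices and degenerate inputs

* Duplicate minutes keep the last value, with a warning; timestamps are
  integer minutes on a half-open session interval.
* A zero-energy (all-constant) window passes through conditioning
  unchanged with zero discarded energy.
* A singular residual covariance is regularized by a jitter of
  `1e-6 · trace/3` before any KL computation.
* Descriptor standardization maps zero-variance coordinates to unit scale.
* Identical training projections collapse phenotype fitting to a single
  cluster with a warning; a zero-variance phenotype imputes its mean
  exactly.
* All randomness flows through explicit integer seeds; identical seed and
  data give bit-identical models, maps and indexes.

## Problem sizes

The shipped tests and the acceptance script run deliberately scaled-down
cohorts chosen once as their stated problem sizes: 32 stable training
sessions of 8 h (about 22 for the map, 10 for calibration), 14 held-out
stable sessions of 12 h (about 10,000 scored minutes) for the false-alarm
rate, and a 36-case/36-control cohort of 8-h sessions with a 4-h
onset-to-event gap for detection. The demonstration pipeline
(`run_pipeline`) uses 12 training and 12 evaluation sessions.

## Known limitations

* The index measures novelty relative to a training *population*; a
  patient whose stable physiology sits at the edge of that population
  scores high without being ill. Larger, representative training cohorts
  are the remedy, as the per-patient false-alarm spread in the tests
  shows.
* The symmetrised KL dissimilarity is a pseudo-metric (no triangle
  inequality) and its scale is dominated by low-variance directions of
  the predictive covariance; the projection consumes it as given.
* The PEW scoring table ships as a structurally valid default (seven
  parameters, maximum 26, alert at 9 or more); its band cut-offs are
  configuration, not a validated chart, and must be replaced with a local
  chart before any clinical use.
* Alarm de-bouncing is off by default (`min_duration = 1` minute), so raw
  alarm counts on noisy patients can be high — consistent with a
  high-sensitivity, low-specificity operating point.
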