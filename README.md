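# rapidindex

Continuous wireless monitoring gives hospitalised children a per-minute
stream of heart rate, respiratory rate and pulse-oximetry — noisy, often
interrupted, and without a single "normal range" that fits a neonate and a
teenager alike. `rapidindex` turns such streams into a per-minute,
patient-adaptive **surprise index**: short windows of the multichannel
signal are conditioned by truncated SVD, modelled as low-order vector
autoregressions, compared by a symmetrised Kullback–Leibler dissimilarity
of their predictive distributions, and embedded in a two-dimensional
topographic (NeuroScale-style RBF) map trained to preserve those
dissimilarities. The local geometry of that map scores each new minute:

```
index(t) = | z(log sqrt(det J Jᵀ)) |  +  max(z(−log p̂(y_t)), 0)
```

where `J` is the map Jacobian at the projected point `y_t` (so
`sqrt(det J Jᵀ)` is the local magnification), `p̂` the kernel density of
the training projections, and `z(·)` a median/MAD z-score against the
training distribution. Minutes at or above a threshold — calibrated as the
95th percentile of the index on held-out stable sessions — form alarms.

Around the index the package provides, for researchers evaluating
early-warning analytics:

* clinical-validity filtering and session quality reports for per-minute
  vital-sign sessions (CSV/JSON I/O);
* a seeded generator of stable and deteriorating paediatric sessions with
  sensor dropout and out-of-range artifact;
* patient *phenotypes* (clusters in the projection space) that supply
  expected-behaviour references and impute sensor gaps of up to 15 min;
* a configurable aggregated Paediatric Early Warning (PEW) score
  (7 parameters, 0–26, alert at ≥ 9) over intermittent observations;
* case-control diagnostic accuracy: exact Clopper–Pearson intervals,
  prevalence-fixed PPV/NPV with Mercaldo logit intervals, McNemar paired
  comparisons, and warning-time summaries.

## Worked example

Simulate a two-sensor session, filter it, and inspect data quality:

```r
library(rapidindex)
s <- generate_session(synthetic_scenario(patient_age_months = 24,
                                         duration_minutes = 600, seed = 7),
                      "demo")
s <- filter_session(s)
s$quality
#> <session_quality> intended 600 min
#>   chest_ecg captured   556 (92.7%)  valid   550 (91.7%)
#>   pulse_ox  captured   331 (55.2%)  valid   326 (54.3%)
```

The chest ECG captured 92.7% of the intended monitoring time and 91.7% was
clinically valid; the pulse oximeter (higher dropout, as is typical for
wrist sensors) captured 55.2%.

Train a model on stable sessions and score a new patient:

```r
train <- generate_cohort(32, 0, seed = 4, duration_minutes = 480)
model <- train_rapid_model(train$sessions, rapid_config(), seed = 1)
idx <- compute_rapid_index(s, model)     # one index value per minute from minute 5
alarms <- generate_alerts(idx)           # runs of minutes >= calibrated threshold
```

Session-level evaluation works from alarm tables and event times. Fed with
the session counts of a 36-case/36-control comparison (35/36 cases
alerted within 72 h, 27/36 controls alerted), the accuracy machinery
prints:

```r
accuracy(contingency_table(35, 1, 27, 9), evaluation_config(prevalence = 0.056))
#> <accuracy_estimates>
#>   Sensitivity; % (95% CI)  97.2 (85.5, 99.9)
#>   Specificity; % (95% CI)  25.0 (12.1, 42.2)
#>   PPV at prevalence 5.6%: 7.1 (5.9, 8.6)
#>   NPV at prevalence 5.6%: 99.3 (95.3, 99.9)
```

— a high-sensitivity, low-specificity operating point: nearly every
deteriorating child is flagged within the window, at the cost of frequent
alarms in stable children, while the high NPV means an alarm-free session
makes significant deterioration unlikely at the assumed 5.6% prevalence.

See `vignettes/rapid-methods.Rmd` for the model, its assumptions, the
synthetic-data design and known limitations.

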