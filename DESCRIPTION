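Package: rapidindex
Title: Patient-Adaptive Surprise Index and Early-Warning Evaluation for
    Paediatric Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for continuous wireless paediatric vital-sign monitoring
    analytics: clinical-validity filtering of per-minute heart rate,
    respiratory rate and pulse-oximetry streams; a seeded generator of
    stable and deteriorating synthetic monitoring sessions; windowed
    singular-vector signal conditioning; per-window vector-autoregressive
    dynamics models with a symmetrised Kullback-Leibler dissimilarity; a
    NeuroScale-style radial-basis-function topographic projection with
    local magnification (curvature) queries; a per-minute patient-adaptive
    surprise index with threshold calibration, alarms, phenotype clustering
    and short-gap imputation; a configurable aggregated Paediatric Early
    Warning score; and case-control diagnostic accuracy statistics
    (exact binomial intervals, prevalence-fixed predictive values with
    Mercaldo logit intervals, McNemar comparisons and warning-time
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
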