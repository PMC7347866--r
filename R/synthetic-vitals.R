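# Latent-stress loading per channel: one shared factor drives HR and RR up
# and SpO2 down, giving the cross-channel interaction structure phenotype
# clustering relies on.
STRESS_LOADING <- c(hr = 6, rr = 3, spo2 = -1)

# Hard physiologic clamps (pre-artifact values must stay inside the clinical
# validity ranges so injected artifacts are recovered exactly by filtering).
PHYS_RANGE <- list(hr = c(30, 250), rr = c(8, 150), spo2 = c(40, 100))

#' Age-dependent vital-sign baselines
#'
#' Resting means and marginal standard deviations as a function of age,
#' interpolated smoothly between paediatric reference points (maturation
#' is gradual, not banded). Editable simulation defaults, not a clinical
#' reference.
#'
#' @param age_months Age in months.
#' @return List with numeric vectors `mean` and `sd` over `hr`, `rr`, `spo2`.
#' @export
age_baseline <- function(age_months) {
  anchor_age <- c(0, 3, 12, 36, 72, 144, 216)
  anchors <- list(hr = c(145, 135, 125, 110, 97, 85, 72),
                  rr = c(48, 40, 32, 26, 22, 18, 15),
                  spo2 = c(97, 97, 97, 97.5, 98, 98, 98))
  m <- vapply(anchors, function(y)
    stats::approx(anchor_age, y, xout = age_months, rule = 2)$y, numeric(1))
  list(mean = m, sd = c(hr = 8, rr = 4, spo2 = 1.2))
}

#' Define a synthetic monitoring scenario
#'
#' Describes one simulated wireless monitoring session: an age-dependent
#' baseline, circadian variation, autocorrelated noise driven by a shared
#' latent stress factor, per-sensor dropout, out-of-range artifact, and an
#' optional deterioration that drifts the vitals away from baseline between
#' an onset and an event.
#'
#' @param patient_age_months Age in months.
#' @param duration_minutes Intended monitoring time (minutes).
#' @param baseline Optional list with `mean`/`sd` per channel; defaults to
#'   [age_baseline()].
#' @param circadian_amplitude Per-channel sinusoidal amplitude (24 h period).
#' @param deterioration `NULL` for a stable session, else a list with
#'   `onset_minute`, `event_minute`, optional `event_type`, and either
#'   `drift_per_hour` (named per-channel rates) or `drift_total` (named
#'   per-channel excursions reached at the event; default hr +40, rr +20,
#'   spo2 -8, reflecting the severe derangement a child shows at a
#'   significant deterioration regardless of how long the decline took).
#'   The linear ramp runs from the onset to the event.
#' @param dropout_rate Named per-sensor minute-wise dropout probabilities.
#'   Defaults 0.07 (chest ECG) and 0.45 (pulse oximeter) reproduce capture
#'   fractions of roughly 93% and 55%.
#' @param artifact_rate Fraction of captured sensor-minutes replaced by
#'   out-of-range values.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(patient_age_months = 24,
                               duration_minutes = 2880,
                               baseline = NULL,
                               circadian_amplitude = c(hr = 5, rr = 2, spo2 = 0.3),
                               deterioration = NULL,
                               dropout_rate = c(chest_ecg = 0.07, pulse_ox = 0.45),
                               artifact_rate = 0.02,
                               seed = 1) {
  if (is.null(baseline)) baseline <- age_baseline(patient_age_months)
  stopifnot(duration_minutes >= 1,
            all(dropout_rate >= 0 & dropout_rate <= 1),
            artifact_rate >= 0, artifact_rate <= 1)
  if (!is.null(deterioration)) {
    if (is.null(deterioration$event_type))
      deterioration$event_type <- "unplanned_picu"
    if (!(deterioration$onset_minute < deterioration$event_minute &&
          deterioration$event_minute <= duration_minutes))
      stopf("deterioration requires onset_minute < event_minute <= duration_minutes")
    if (is.null(deterioration$drift_per_hour)) {
      if (is.null(deterioration$drift_total))
        deterioration$drift_total <- c(hr = 40, rr = 20, spo2 = -8)
      gap_hours <- (deterioration$event_minute -
                      deterioration$onset_minute) / 60
      deterioration$drift_per_hour <- deterioration$drift_total / gap_hours
    }
  }
  structure(list(patient_age_months = patient_age_months,
                 duration_minutes = duration_minutes,
                 baseline = baseline,
                 circadian_amplitude = circadian_amplitude,
                 deterioration = deterioration,
                 dropout_rate = dropout_rate,
                 artifact_rate = artifact_rate,
                 seed = seed),
            class = "synthetic_scenario")
}

#' Generate one synthetic monitoring session
#'
#' Stable dynamics are per-channel AR(1) noise around the (circadian)
#' baseline plus a shared latent AR(1) stress factor loading HR and RR
#' positively and SpO2 negatively. Deterioration adds a linear per-channel
#' drift from the onset minute. Values are clamped to physiologic ranges,
#' then per-sensor dropout removes minutes and artifact minutes are
#' replaced by values outside the clinical validity ranges. The injected
#' artifact minutes are recorded in `attr(, "injected_artifacts")` and the
#' pre-dropout clean series in `attr(, "clean_values")`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param session_id Session identifier.
#' @return A [monitoring_session()] (with a deterioration annotation when
#'   the scenario configures one).
#' @export
generate_session <- function(scenario, session_id = "synthetic") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    T_int <- scenario$duration_minutes
    t <- seq_len(T_int) - 1L
    bl <- scenario$baseline

    # shared latent stress factor, stationary sd 1
    phi_s <- 0.95
    s <- stats::filter(stats::rnorm(T_int, 0, sqrt(1 - phi_s^2)), phi_s,
                       method = "recursive")
    s <- as.numeric(s)

    drift <- matrix(0, T_int, 3, dimnames = list(NULL, CHANNELS))
    det <- scenario$deterioration
    if (!is.null(det)) {
      post <- pmax(0, t - det$onset_minute)
      for (ch in CHANNELS)
        drift[, ch] <- det$drift_per_hour[[ch]] * post / 60
    }

    clean <- matrix(NA_real_, T_int, 3, dimnames = list(NULL, CHANNELS))
    phi_e <- 0.9
    circ <- sin(2 * pi * (t + 480) / 1440)
    for (ch in CHANNELS) {
      e <- as.numeric(stats::filter(
        stats::rnorm(T_int, 0, bl$sd[[ch]] * 0.6 * sqrt(1 - phi_e^2)),
        phi_e, method = "recursive"))
      x <- bl$mean[[ch]] + scenario$circadian_amplitude[[ch]] * circ +
        STRESS_LOADING[[ch]] * s + e + drift[, ch]
      rng <- PHYS_RANGE[[ch]]
      clean[, ch] <- pmin(pmax(x, rng[1]), rng[2])
    }
    clean <- round(clean)
    pr_clean <- round(pmin(pmax(clean[, "hr"] + stats::rnorm(T_int, 0, 1),
                                PHYS_RANGE$hr[1]), PHYS_RANGE$hr[2]))

    captured <- cbind(
      chest_ecg = stats::runif(T_int) >= scenario$dropout_rate[["chest_ecg"]],
      pulse_ox  = stats::runif(T_int) >= scenario$dropout_rate[["pulse_ox"]])

    # artifacts: per captured sensor-minute, replace with out-of-range values
    art <- cbind(
      chest_ecg = captured[, "chest_ecg"] & stats::runif(T_int) < scenario$artifact_rate,
      pulse_ox  = captured[, "pulse_ox"] & stats::runif(T_int) < scenario$artifact_rate)

    hr <- ifelse(captured[, "chest_ecg"], clean[, "hr"], NA_real_)
    rr <- ifelse(captured[, "chest_ecg"], clean[, "rr"], NA_real_)
    spo2 <- ifelse(captured[, "pulse_ox"], clean[, "spo2"], NA_real_)
    pr <- ifelse(captured[, "pulse_ox"], pr_clean, NA_real_)
    hr[art[, "chest_ecg"]] <- sample(c(5, 350), sum(art[, "chest_ecg"]), replace = TRUE)
    rr[art[, "chest_ecg"]] <- sample(c(2, 250), sum(art[, "chest_ecg"]), replace = TRUE)
    spo2[art[, "pulse_ox"]] <- sample(c(5, 20), sum(art[, "pulse_ox"]), replace = TRUE)
    pr[art[, "pulse_ox"]] <- sample(c(10, 350), sum(art[, "pulse_ox"]), replace = TRUE)

    keep <- captured[, "chest_ecg"] | captured[, "pulse_ox"]
    samples <- data.frame(minute = t, hr = hr, rr = rr, spo2 = spo2, pr = pr)[keep, ]

    ann <- NULL
    if (!is.null(det))
      ann <- data.frame(session_id = session_id,
                        onset_minute = det$onset_minute,
                        event_minute = det$event_minute,
                        event_type = det$event_type,
                        stringsAsFactors = FALSE)
    sess <- monitoring_session(session_id, scenario$patient_age_months, samples,
                               intended_start = 0, intended_end = T_int,
                               annotations = ann)
    attr(sess, "injected_artifacts") <-
      data.frame(minute = c(t[art[, "chest_ecg"]], t[art[, "pulse_ox"]]),
                 sensor = rep(c("chest_ecg", "pulse_ox"),
                              c(sum(art[, "chest_ecg"]), sum(art[, "pulse_ox"]))))
    attr(sess, "clean_values") <- clean
    sess
  })
}

#' Generate a case-control cohort of synthetic sessions
#'
#' Deteriorating (case) sessions place their event at the session end with
#' an onset-to-event gap drawn around a 47 h median (truncated to fit the
#' session); stable (control) sessions have no event. Ages are sampled by
#' stratified uniform draws over the paediatric range (one draw per
#' equal-width age bin, then shuffled), so every cohort is representative
#' of the full range the way a deliberately assembled training sample
#' would be. Fully reproducible from the seed.
#'
#' @param n_stable,n_deteriorating Session counts (either may be 0, not both).
#' @param seed Integer seed.
#' @param duration_minutes Intended duration of every session.
#' @param gap_hours_mean,gap_hours_sd Normal onset-to-event gap (hours),
#'   truncated to `[1h, 0.9 * duration]`.
#' @param ... Passed to [synthetic_scenario()] (e.g. `dropout_rate`,
#'   `artifact_rate`).
#' @return List with `sessions` (list of [monitoring_session()]) and
#'   `events` (data frame `session_id,onset_minute,event_minute,event_type`).
#' @export
generate_cohort <- function(n_stable, n_deteriorating, seed = 1,
                            duration_minutes = 5760,
                            gap_hours_mean = 47, gap_hours_sd = 10, ...) {
  stopifnot(n_stable >= 0, n_deteriorating >= 0,
            n_stable + n_deteriorating >= 1)
  with_seed(seed, {
    n <- n_stable + n_deteriorating
    edges <- seq(1, 192, length.out = n + 1)
    ages <- sample(stats::runif(n, edges[-(n + 1)], edges[-1]))
    seeds <- sample.int(1e6, n)
    is_case <- rep(c(FALSE, TRUE), c(n_stable, n_deteriorating))
    gaps <- pmin(pmax(stats::rnorm(n, gap_hours_mean, gap_hours_sd) * 60, 60),
                 0.9 * duration_minutes)
    event_types <- sample(c("cardiac_arrest", "respiratory_arrest",
                            "life_threatening", "unplanned_picu"),
                          n, replace = TRUE, prob = c(.1, .1, .2, .6))
    sessions <- vector("list", n)
    events <- list()
    for (i in seq_len(n)) {
      id <- sprintf("%s-%03d", if (is_case[i]) "case" else "control", i)
      det <- NULL
      if (is_case[i])
        det <- list(onset_minute = round(duration_minutes - gaps[i]),
                    event_minute = duration_minutes,
                    event_type = event_types[i])
      sc <- synthetic_scenario(patient_age_months = ages[i],
                               duration_minutes = duration_minutes,
                               deterioration = det, seed = seeds[i], ...)
      sessions[[i]] <- generate_session(sc, session_id = id)
      if (is_case[i]) events[[length(events) + 1L]] <- sessions[[i]]$annotations
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(session_id = character(), onset_minute = numeric(),
                 event_minute = numeric(), event_type = character())
    list(sessions = sessions, events = events)
  })
}
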