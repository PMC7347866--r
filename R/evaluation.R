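#' Evaluation configuration
#'
#' @param detection_window_hours Window before the event within which a
#'   case alert counts as detection (24 or 72 in the study design).
#' @param prevalence Assumed true prevalence for the predictive values.
#' @return A list of class `evaluation_config`.
#' @export
evaluation_config <- function(detection_window_hours = 72,
                              prevalence = 0.056) {
  stopifnot(detection_window_hours > 0,
            prevalence > 0, prevalence < 1)
  structure(list(detection_window_hours = detection_window_hours,
                 prevalence = prevalence),
            class = "evaluation_config")
}

#' Session-level contingency table
#'
#' @param tp,fn,fp,tn Non-negative integer counts; `tp + fn` is the number
#'   of case sessions and `fp + tn` the number of control sessions.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> tp=%d fn=%d fp=%d tn=%d (cases %d, controls %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn, x$fp + x$tn))
  invisible(x)
}

first_alert_in_window <- function(alerts, event_minute, window_minutes) {
  if (is.null(alerts) || nrow(alerts) == 0) return(NA_real_)
  lo <- event_minute - window_minutes
  # an alert qualifies if any alerted minute falls in [event - window, event]
  hit <- alerts$end_minute >= lo & alerts$start_minute <= event_minute
  if (!any(hit)) return(NA_real_)
  max(min(alerts$start_minute[hit]), lo)
}

#' Classify sessions into a contingency table
#'
#' Cases (sessions with an event) count as true positive iff at least one
#' alert falls within the detection window before their event, else false
#' negative; controls count as false positive iff they have any alert,
#' else true negative.
#'
#' @param case_alerts,control_alerts Data frames of alarm events
#'   (`session_id`, `start_minute`, `end_minute`), e.g. from
#'   [generate_alerts()]; sessions without alerts simply have no rows.
#' @param events Data frame with one row per case session:
#'   `session_id`, `event_minute`.
#' @param control_ids Character vector of all control session ids
#'   (required so alert-free controls are counted).
#' @param cfg An [evaluation_config()].
#' @return A [contingency_table()].
#' @export
classify_sessions <- function(case_alerts, control_alerts, events,
                              control_ids, cfg = evaluation_config()) {
  if (anyNA(events$event_minute))
    stopf("every case session needs an event time")
  if (anyDuplicated(events$session_id))
    stopf("one event row per case session expected")
  w <- cfg$detection_window_hours * 60
  tp <- sum(vapply(seq_len(nrow(events)), function(i) {
    a <- case_alerts[case_alerts$session_id == events$session_id[i], ,
                     drop = FALSE]
    !is.na(first_alert_in_window(a, events$event_minute[i], w))
  }, logical(1)))
  fp <- sum(control_ids %in% control_alerts$session_id)
  contingency_table(tp, nrow(events) - tp, fp, length(control_ids) - fp)
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

# Prevalence-fixed predictive values with logit-transformed intervals
# (Mercaldo, Lau & Zhou 2007 construction).
mercaldo_pv <- function(se, sp, n1, n0, prev, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ppv <- se * prev / (se * prev + (1 - sp) * (1 - prev))
  npv <- sp * (1 - prev) / ((1 - se) * prev + sp * (1 - prev))
  inv <- function(l) 1 / (1 + exp(-l))
  ppv_ci <- if (sp < 1 && se > 0) {
    l <- log(prev * se / ((1 - prev) * (1 - sp)))
    v <- (1 - se) / (se * n1) + sp / ((1 - sp) * n0)
    inv(l + c(-1, 1) * z * sqrt(v))
  } else c(NA_real_, NA_real_)
  npv_ci <- if (se < 1 && sp > 0) {
    l <- log((1 - prev) * sp / (prev * (1 - se)))
    v <- se / ((1 - se) * n1) + (1 - sp) / (sp * n0)
    inv(l + c(-1, 1) * z * sqrt(v))
  } else c(NA_real_, NA_real_)
  list(ppv = ppv, ppv_ci = ppv_ci, npv = npv, npv_ci = npv_ci)
}

#' Diagnostic accuracy with exact and prevalence-fixed intervals
#'
#' Sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` with exact
#' Clopper-Pearson 95% intervals, and PPV/NPV computed at a fixed assumed
#' prevalence with Mercaldo logit-transformed intervals:
#' `PPV = se*pi / (se*pi + (1-sp)(1-pi))` and
#' `NPV = sp(1-pi) / ((1-se)pi + sp(1-pi))`.
#'
#' @param table A [contingency_table()].
#' @param cfg An [evaluation_config()] supplying the prevalence.
#' @return An `accuracy_estimates` object: `sensitivity`, `specificity`,
#'   `ppv`, `npv` (each a list with `estimate` and `ci`), plus the
#'   prevalence used.
#' @export
accuracy <- function(table, cfg = evaluation_config()) {
  n1 <- table$tp + table$fn
  n0 <- table$tn + table$fp
  if (n1 == 0) stopf("sensitivity undefined: no case sessions")
  if (n0 == 0) stopf("specificity undefined: no control sessions")
  se <- table$tp / n1
  sp <- table$tn / n0
  pv <- mercaldo_pv(se, sp, n1, n0, cfg$prevalence)
  structure(list(
    sensitivity = list(estimate = se, ci = clopper_pearson(table$tp, n1)),
    specificity = list(estimate = sp, ci = clopper_pearson(table$tn, n0)),
    ppv = list(estimate = pv$ppv, ci = pv$ppv_ci),
    npv = list(estimate = pv$npv, ci = pv$npv_ci),
    prevalence = cfg$prevalence,
    table = table), class = "accuracy_estimates")
}

#' @export
print.accuracy_estimates <- function(x, ...) {
  fmt <- function(e) sprintf("%.1f (%.1f, %.1f)", 100 * e$estimate,
                             100 * e$ci[1], 100 * e$ci[2])
  cat("<accuracy_estimates>\n")
  cat("  Sensitivity; % (95% CI) ", fmt(x$sensitivity), "\n")
  cat("  Specificity; % (95% CI) ", fmt(x$specificity), "\n")
  cat(sprintf("  PPV at prevalence %.1f%%: %s\n", 100 * x$prevalence, fmt(x$ppv)))
  cat(sprintf("  NPV at prevalence %.1f%%: %s\n", 100 * x$prevalence, fmt(x$npv)))
  invisible(x)
}

#' Paired comparison of two alerting methods
#'
#' Differences in sensitivity and specificity between methods A and B on
#' the same sessions (`proportion_B - proportion_A`), with McNemar tests
#' on the discordant pairs: exact two-sided binomial when fewer than 25
#' pairs are discordant, otherwise the continuity-corrected chi-square.
#' Wald confidence intervals for the paired differences.
#'
#' @param case_flags_a,case_flags_b Logical alert flags per case session.
#' @param control_flags_a,control_flags_b Logical alert flags per control
#'   session.
#' @return List with `sensitivity` and `specificity` components, each
#'   holding `difference`, `ci`, `mcnemar_statistic` (NA for the exact
#'   test), `p_value` and `method`.
#' @export
compare_paired <- function(case_flags_a, case_flags_b,
                           control_flags_a, control_flags_b) {
  if (length(case_flags_a) != length(case_flags_b) ||
      length(control_flags_a) != length(control_flags_b))
    stopf("paired flag vectors must have equal length")
  one <- function(a, b) {
    n <- length(a)
    d <- mean(b) - mean(a)
    b10 <- sum(a & !b)
    b01 <- sum(!a & b)
    disc <- b10 + b01
    if (disc == 0) {
      stat <- NA_real_; p <- 1; method <- "exact"
    } else if (disc < 25) {
      stat <- NA_real_
      p <- min(1, 2 * stats::pbinom(min(b10, b01), disc, 0.5))
      method <- "exact"
    } else {
      stat <- (abs(b10 - b01) - 1)^2 / disc
      p <- stats::pchisq(stat, 1, lower.tail = FALSE)
      method <- "chi-square"
    }
    sd_d <- sqrt(pmax(disc - (b10 - b01)^2 / n, 0)) / n
    list(difference = d, ci = d + c(-1, 1) * stats::qnorm(0.975) * sd_d,
         mcnemar_statistic = stat, p_value = p, method = method)
  }
  list(sensitivity = one(case_flags_a, case_flags_b),
       # specificity flags are "no alert" on controls
       specificity = one(!control_flags_a, !control_flags_b))
}

#' Summarise warning times
#'
#' Time from the first qualifying alert (within the detection window
#' before the event) to the event, in hours, per event; events never
#' alerted are excluded and `n` reflects that. Quartiles use inclusive
#' linear interpolation.
#'
#' @param alert_streams Data frame of alarm events across case sessions
#'   (`session_id`, `start_minute`, `end_minute`).
#' @param events Data frame `session_id`, `event_minute`.
#' @param cfg An [evaluation_config()].
#' @return A `warning_time_summary`.
#' @export
warning_times <- function(alert_streams, events, cfg = evaluation_config()) {
  w <- cfg$detection_window_hours * 60
  times <- vapply(seq_len(nrow(events)), function(i) {
    a <- alert_streams[alert_streams$session_id == events$session_id[i], ,
                       drop = FALSE]
    first <- first_alert_in_window(a, events$event_minute[i], w)
    (events$event_minute[i] - first) / 60
  }, numeric(1))
  warning_time_summary(times[!is.na(times)])
}

#' @rdname warning_times
#' @param times_hours Numeric vector of warning times in hours.
#' @export
warning_time_summary <- function(times_hours) {
  n <- length(times_hours)
  q <- if (n) stats::quantile(times_hours, c(.25, .5, .75), type = 7,
                              names = FALSE) else rep(NA_real_, 3)
  structure(list(n = n,
                 total = sum(times_hours),
                 mean = if (n) mean(times_hours) else NA_real_,
                 min = if (n) min(times_hours) else NA_real_,
                 q1 = q[1], median = q[2], q3 = q[3],
                 max = if (n) max(times_hours) else NA_real_),
            class = "warning_time_summary")
}

#' @export
print.warning_time_summary <- function(x, ...) {
  cat(sprintf("<warning_time_summary> n=%d total=%.1f mean=%.1f h [min %.1f, Q1 %.1f, median %.1f, Q3 %.1f, max %.1f]\n",
              x$n, x$total, x$mean, x$min, x$q1, x$median, x$q3, x$max))
  invisible(x)
}
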