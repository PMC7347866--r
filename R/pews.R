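#' Paediatric Early Warning scoring table
#'
#' A scoring table maps each of the seven bedside parameters (respiratory
#' rate, respiratory distress, pulse-oximetry, inspired oxygen, heart
#' rate, systolic blood pressure, capillary refill time) through age-banded
#' value bands to non-negative integer subscores; the subscore maxima sum
#' to 26 and a total of `alert_threshold` (default 9) or more triggers an
#' alert. The shipped default table satisfies this structure; its band
#' cut-offs are editable configuration, not a validated clinical chart.
#'
#' `read_pews_table()`/`write_pews_table()` use a YAML schema: top-level
#' `alert_threshold`, `max_total`, and `age_bands`, each age band holding
#' `max_age_months` and per-parameter lists of `[min, max, score]` bands
#' (half-open `[min, max)`, `.inf` allowed).
#'
#' @param path YAML file path.
#' @return A `pews_table` object.
#' @export
read_pews_table <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- structure(raw, class = "pews_table")
  validate_pews_table(tab)
  tab
}

#' @rdname read_pews_table
#' @param table A `pews_table`.
#' @export
write_pews_table <- function(table, path) {
  yaml::write_yaml(unclass(table), path)
  invisible(path)
}

#' @rdname read_pews_table
#' @export
pews_default_table <- function() {
  read_pews_table(system.file("extdata", "pews_default.yaml",
                              package = "rapidindex", mustWork = TRUE))
}

PEWS_PARAMS <- c("respiratory_rate", "respiratory_distress", "spo2",
                 "inspired_oxygen", "heart_rate", "systolic_bp",
                 "capillary_refill_seconds")

validate_pews_table <- function(tab) {
  stopifnot(!is.null(tab$age_bands), length(tab$age_bands) >= 1)
  for (band in tab$age_bands) {
    maxima <- vapply(PEWS_PARAMS, function(p) {
      bands <- band$parameters[[p]]
      if (is.null(bands)) stopf("scoring table misses parameter '%s'", p)
      lo <- vapply(bands, function(b) as.numeric(b[[1]]), numeric(1))
      hi <- vapply(bands, function(b) as.numeric(b[[2]]), numeric(1))
      sc <- vapply(bands, function(b) as.numeric(b[[3]]), numeric(1))
      if (any(sc < 0) || any(sc != round(sc)))
        stopf("subscores must be non-negative integers ('%s')", p)
      o <- order(lo)
      if (lo[o][1] != -Inf || hi[o][length(hi)] != Inf ||
          any(hi[o][-length(hi)] != lo[o][-1]))
        stopf("bands for '%s' must partition (-Inf, Inf)", p)
      max(sc)
    }, numeric(1))
    if (sum(maxima) != tab$max_total)
      stopf("subscore maxima sum to %d, expected %d", sum(maxima), tab$max_total)
  }
  invisible(tab)
}

pews_band_for_age <- function(tab, age_months) {
  maxes <- vapply(tab$age_bands, function(b) as.numeric(b$max_age_months),
                  numeric(1))
  idx <- which(maxes > age_months)[1]
  if (is.na(idx)) idx <- length(maxes)
  tab$age_bands[[idx]]
}

#' Compute an aggregated PEW score
#'
#' Sums the age-banded subscores of the seven parameters. Missing
#' parameters contribute 0 with a completeness warning; a value that falls
#' in no band raises an error naming the parameter (a valid table is
#' total, so this indicates a broken table).
#'
#' @param obs A list or one-row data frame with (any of) the parameters
#'   named in the table; `inspired_oxygen` is a fraction (0.21 = room air)
#'   and `respiratory_distress` an ordinal 0-3.
#' @param table A `pews_table` (default [pews_default_table()]).
#' @param age_months Patient age in months.
#' @return Integer score in 0..26 with attribute `subscores`.
#' @export
compute_pews <- function(obs, table = pews_default_table(), age_months) {
  band <- pews_band_for_age(table, age_months)
  subscores <- vapply(PEWS_PARAMS, function(p) {
    v <- obs[[p]]
    if (is.null(v) || length(v) == 0 || is.na(v)) return(NA_real_)
    for (b in band$parameters[[p]]) {
      lo <- as.numeric(b[[1]]); hi <- as.numeric(b[[2]])
      if (v >= lo && v < hi) return(as.numeric(b[[3]]))
    }
    stopf("value %s for '%s' falls outside all scoring bands", v, p)
  }, numeric(1))
  if (anyNA(subscores))
    warnf("incomplete observation; %s scored as 0",
          paste(PEWS_PARAMS[is.na(subscores)], collapse = ", "))
  score <- as.integer(sum(subscores, na.rm = TRUE))
  attr(score, "subscores") <- subscores
  score
}

#' Alert series over intermittent PEW observations
#'
#' Scores each observation and reports the timestamps at which the total
#' reaches the alert threshold.
#'
#' @param observations Data frame with a `timestamp` column plus the PEW
#'   parameters, sorted by timestamp.
#' @param table A `pews_table`.
#' @param age_months Patient age in months.
#' @param threshold Alert threshold (default the table's, 9).
#' @return Data frame with `timestamp` and `score` of alerting
#'   observations.
#' @export
pews_alert_series <- function(observations, table = pews_default_table(),
                              age_months, threshold = NULL) {
  if (is.null(threshold)) threshold <- table$alert_threshold
  if (nrow(observations) == 0)
    return(data.frame(timestamp = numeric(0), score = integer(0)))
  if (is.unsorted(observations$timestamp))
    stopf("observations must be sorted by timestamp")
  scores <- vapply(seq_len(nrow(observations)), function(i)
    as.integer(compute_pews(observations[i, , drop = FALSE], table,
                            age_months)), integer(1))
  keep <- scores >= threshold
  data.frame(timestamp = observations$timestamp[keep], score = scores[keep])
}
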