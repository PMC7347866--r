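#' Clinical validity ranges for wireless vital signs
#'
#' Broad per-channel filters used to exclude technical noise from wireless
#' streams: heart rate (and pulse rate) below `hr_min` or above `hr_max`
#' beats/min, respiratory rate below `rr_min` or above `rr_max` breaths/min,
#' and pulse-oximetry below `spo2_min` percent are flagged invalid. Bounds
#' are exclusive: a value exactly at a bound is valid.
#'
#' @param hr_min,hr_max Heart-rate bounds (beats/min).
#' @param rr_min,rr_max Respiratory-rate bounds (breaths/min).
#' @param spo2_min Pulse-oximetry lower bound (percent).
#' @return An object of class `validity_config`.
#' @examples
#' cfg <- validity_config()
#' validate_sample(list(hr = 19, rr = 25, spo2 = 98), cfg)
#' @export
validity_config <- function(hr_min = 20, hr_max = 300,
                            rr_min = 5, rr_max = 200,
                            spo2_min = 30) {
  stopifnot(hr_min > 0, rr_min > 0, spo2_min > 0,
            hr_min < hr_max, rr_min < rr_max)
  structure(list(hr_min = hr_min, hr_max = hr_max,
                 rr_min = rr_min, rr_max = rr_max,
                 spo2_min = spo2_min),
            class = "validity_config")
}

channel_bounds <- function(cfg) {
  # pr is carried and filtered with the heart-rate bounds
  list(hr   = c(cfg$hr_min, cfg$hr_max),
       rr   = c(cfg$rr_min, cfg$rr_max),
       spo2 = c(cfg$spo2_min, Inf),
       pr   = c(cfg$hr_min, cfg$hr_max))
}

#' Per-channel validity flags for one vital-sign sample
#'
#' A channel is `"invalid"` iff it is present and strictly outside its
#' configured range, `"missing"` if absent (`NULL` or `NA`), otherwise
#' `"valid"`. Total function: never errors on numeric input.
#'
#' @param sample A list or one-row data frame with any of `hr`, `rr`,
#'   `spo2`, `pr`.
#' @param cfg A [validity_config()].
#' @return Named character vector over `hr`, `rr`, `spo2`, `pr`.
#' @export
validate_sample <- function(sample, cfg = validity_config()) {
  bounds <- channel_bounds(cfg)
  out <- vapply(ALL_CHANNELS, function(ch) {
    v <- sample[[ch]]
    if (is.null(v) || length(v) == 0 || is.na(v)) return("missing")
    b <- bounds[[ch]]
    if (v < b[1] || v > b[2]) "invalid" else "valid"
  }, character(1))
  out
}

#' Construct a per-minute monitoring session
#'
#' Samples are one row per minute with columns `minute`, `hr`, `rr`,
#' `spo2`, `pr` (`NA` = channel missing that minute). Rows are sorted by
#' minute; duplicated minutes keep the last row with a warning. The session
#' interval is half-open: minutes run over `[intended_start, intended_end)`.
#'
#' @param session_id Character identifier.
#' @param patient_age_months Age in months (>= 0).
#' @param samples Data frame of per-minute samples.
#' @param intended_start,intended_end Session bounds in minutes.
#' @param annotations Optional data frame of deterioration events with
#'   columns `onset_minute`, `event_minute`, `event_type`.
#' @return An object of class `monitoring_session`.
#' @export
monitoring_session <- function(session_id, patient_age_months, samples,
                               intended_start = 0,
                               intended_end = NULL,
                               annotations = NULL) {
  stopifnot(is.data.frame(samples),
            is.na(patient_age_months) || patient_age_months >= 0)
  for (ch in ALL_CHANNELS)
    if (is.null(samples[[ch]])) samples[[ch]] <- rep(NA_real_, nrow(samples))
  if (is.null(samples$minute)) stopf("samples must have a 'minute' column")
  samples <- samples[, c("minute", ALL_CHANNELS)]
  if (anyNA(samples$minute) || any(samples$minute < intended_start))
    stopf("sample minutes must be >= intended_start and non-missing")
  if (is.unsorted(samples$minute))
    samples <- samples[order(samples$minute), , drop = FALSE]
  if (anyDuplicated(samples$minute)) {
    warnf("duplicate minutes in session '%s'; keeping last value", session_id)
    samples <- samples[!duplicated(samples$minute, fromLast = TRUE), ,
                       drop = FALSE]
  }
  if (is.null(intended_end)) intended_end <- max(samples$minute) + 1
  if (intended_end <= intended_start)
    stopf("intended_end must be greater than intended_start")
  if (!is.null(annotations)) {
    stopifnot(all(annotations$onset_minute <= annotations$event_minute))
  }
  rownames(samples) <- NULL
  structure(list(session_id = as.character(session_id),
                 patient_age_months = patient_age_months,
                 intended_start = intended_start,
                 intended_end = intended_end,
                 samples = samples,
                 validity = NULL,
                 quality = NULL,
                 annotations = annotations),
            class = "monitoring_session")
}

#' @export
print.monitoring_session <- function(x, ...) {
  cat(sprintf("<monitoring_session '%s'>\n", x$session_id))
  cat(sprintf("  age %s months; intended [%d, %d) = %d min; %d sampled minutes\n",
              format(x$patient_age_months), x$intended_start, x$intended_end,
              x$intended_end - x$intended_start, nrow(x$samples)))
  if (!is.null(x$quality)) {
    q <- x$quality
    cat(sprintf("  filtered: chest_ecg %.0f%% captured / %.0f%% valid; pulse_ox %.0f%% / %.0f%%\n",
                100 * q$proportion_captured[["chest_ecg"]],
                100 * q$proportion_valid[["chest_ecg"]],
                100 * q$proportion_captured[["pulse_ox"]],
                100 * q$proportion_valid[["pulse_ox"]]))
  }
  if (!is.null(x$annotations))
    cat(sprintf("  %d deterioration event(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Apply clinical-validity filtering to a session
#'
#' Computes a per-sample, per-channel validity mask and a session quality
#' report. Filtering is idempotent; the report expresses captured and valid
#' minutes per sensor as counts and as proportions of intended monitoring
#' time.
#'
#' @param session A [monitoring_session()].
#' @param cfg A [validity_config()].
#' @return The session with `validity` (character matrix, one row per
#'   sample, columns `hr`,`rr`,`spo2`,`pr`, values `valid`/`invalid`/
#'   `missing`) and `quality` (class `session_quality`) filled in.
#' @export
filter_session <- function(session, cfg = validity_config()) {
  stopifnot(inherits(session, "monitoring_session"))
  if (nrow(session$samples) == 0)
    stopf("session '%s' has no samples to filter", session$session_id)
  bounds <- channel_bounds(cfg)
  vals <- as.matrix(session$samples[, ALL_CHANNELS])
  validity <- matrix("missing", nrow(vals), ncol(vals),
                     dimnames = list(NULL, ALL_CHANNELS))
  for (ch in ALL_CHANNELS) {
    v <- vals[, ch]
    present <- !is.na(v)
    b <- bounds[[ch]]
    validity[present, ch] <-
      ifelse(v[present] < b[1] | v[present] > b[2], "invalid", "valid")
  }
  intended <- session$intended_end - session$intended_start

  per_sensor <- function(chs) {
    sub <- validity[, chs, drop = FALSE]
    present <- rowSums(sub != "missing") > 0
    invalid <- present & rowSums(sub == "invalid") > 0
    captured <- sum(present)
    c(captured = captured, valid = captured - sum(invalid))
  }
  cnt <- vapply(SENSORS, per_sensor, numeric(2))
  quality <- structure(list(
    intended_minutes = intended,
    captured_minutes = cnt["captured", ],
    valid_minutes = cnt["valid", ],
    proportion_captured = cnt["captured", ] / intended,
    proportion_valid = cnt["valid", ] / intended
  ), class = "session_quality")

  session$validity <- validity
  session$quality <- quality
  session
}

#' @export
print.session_quality <- function(x, ...) {
  cat(sprintf("<session_quality> intended %d min\n", x$intended_minutes))
  for (s in names(SENSORS))
    cat(sprintf("  %-9s captured %5d (%.1f%%)  valid %5d (%.1f%%)\n", s,
                x$captured_minutes[[s]], 100 * x$proportion_captured[[s]],
                x$valid_minutes[[s]], 100 * x$proportion_valid[[s]]))
  invisible(x)
}

# Valid values on the full minute grid: T x 3 matrix (hr, rr, spo2), NA where
# a minute is missing or flagged invalid. Used by the feature pipeline.
session_grid <- function(session) {
  stopifnot(!is.null(session$validity))
  T_int <- session$intended_end - session$intended_start
  grid <- matrix(NA_real_, T_int, length(CHANNELS),
                 dimnames = list(NULL, CHANNELS))
  idx <- session$samples$minute - session$intended_start + 1L
  keep <- idx >= 1L & idx <= T_int
  for (ch in CHANNELS) {
    ok <- keep & session$validity[, ch] == "valid"
    grid[idx[ok], ch] <- session$samples[[ch]][ok]
  }
  grid
}

#' Read or write a monitoring session
#'
#' CSV files carry columns `minute,hr,rr,spo2,pr` (empty cell = missing)
#' with session metadata and any deterioration events in leading `#`
#' comment lines; JSON mirrors the full session object. Writing then
#' reading restores all fields. Non-monotone timestamps are sorted on read
#' with a warning; unknown columns are dropped with a warning; malformed
#' rows raise an error naming the row.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return A [monitoring_session()].
#' @export
read_session <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stopf("no such session file: %s", path)
  if (format == "json")
    return(session_from_list(jsonlite::fromJSON(path, simplifyDataFrame = TRUE)))

  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  events <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "event") events[[length(events) + 1L]] <- val else meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  tc <- textConnection(body)
  on.exit(close(tc))
  df <- utils::read.csv(tc, stringsAsFactors = FALSE)
  known <- c("minute", ALL_CHANNELS)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warnf("ignoring unknown column(s): %s", paste(extra, collapse = ", "))
    df <- df[, intersect(names(df), known), drop = FALSE]
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad))
        stopf("malformed value in column '%s' at data row %d of %s",
              col, bad[1], path)
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  if (is.unsorted(df$minute)) warnf("timestamps not monotone in %s; sorting", path)
  ann <- NULL
  if (length(events)) {
    parts <- do.call(rbind, lapply(events, function(e) strsplit(e, ",")[[1]]))
    ann <- data.frame(session_id = meta$session_id %||% basename(path),
                      onset_minute = as.numeric(parts[, 1]),
                      event_minute = as.numeric(parts[, 2]),
                      event_type = trimws(parts[, 3]),
                      stringsAsFactors = FALSE)
  }
  monitoring_session(
    session_id = meta$session_id %||% basename(path),
    patient_age_months = as.numeric(meta$patient_age_months %||% NA),
    samples = df,
    intended_start = as.numeric(meta$intended_start %||% 0),
    intended_end = if (is.null(meta$intended_end)) NULL else as.numeric(meta$intended_end),
    annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_session
#' @param session A [monitoring_session()] to write.
#' @export
write_session <- function(session, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(session_to_list(session), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    return(invisible(path))
  }
  hdr <- c(sprintf("# session_id: %s", session$session_id),
           sprintf("# patient_age_months: %s", session$patient_age_months),
           sprintf("# intended_start: %s", session$intended_start),
           sprintf("# intended_end: %s", session$intended_end))
  if (!is.null(session$annotations))
    hdr <- c(hdr, sprintf("# event: %s,%s,%s",
                          session$annotations$onset_minute,
                          session$annotations$event_minute,
                          session$annotations$event_type))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(session$samples, con, row.names = FALSE, na = "")
  invisible(path)
}

session_to_list <- function(session) {
  list(session_id = session$session_id,
       patient_age_months = session$patient_age_months,
       intended_start = session$intended_start,
       intended_end = session$intended_end,
       samples = session$samples,
       annotations = session$annotations)
}

session_from_list <- function(x) {
  samples <- as.data.frame(x$samples)
  for (col in names(samples)) samples[[col]] <- as.numeric(samples[[col]])
  ann <- if (!is.null(x$annotations) && NROW(x$annotations) > 0)
    as.data.frame(x$annotations) else NULL
  monitoring_session(x$session_id, x$patient_age_months, samples,
                     intended_start = x$intended_start,
                     intended_end = x$intended_end,
                     annotations = ann)
}
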