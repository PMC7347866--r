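#' Per-channel training statistics
#'
#' Mean and standard deviation of each channel over the valid minutes of a
#' set of filtered sessions. Frozen at training time so that new patients
#' are standardized onto the same scale as the training phenotype space.
#'
#' @param sessions List of filtered [monitoring_session()] objects.
#' @return List with numeric vectors `mean` and `sd` over `hr`,`rr`,`spo2`.
#' @export
channel_stats <- function(sessions) {
  grids <- lapply(sessions, session_grid)
  all <- do.call(rbind, grids)
  m <- colMeans(all, na.rm = TRUE)
  s <- apply(all, 2, stats::sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

# Limited last-observation-carried-forward down a column.
locf_limited <- function(x, limit) {
  n <- length(x)
  if (n == 0 || limit <= 0) return(x)
  run <- 0L
  last <- NA_real_
  for (i in seq_len(n)) {
    if (is.na(x[i])) {
      run <- run + 1L
      if (!is.na(last) && run <= limit) x[i] <- last
    } else {
      last <- x[i]
      run <- 0L
    }
  }
  x
}

#' Cut a session into sliding windows
#'
#' Windows of `window_len` contiguous minutes at the given stride over the
#' full intended grid of valid values (hr, rr, spo2). Gaps are filled by
#' last-observation-carried-forward up to `locf_limit` minutes;
#' `completeness` is the fraction of cells observed before fill-in, and a
#' window is usable when it is at least `completeness_floor` complete and
#' fully filled.
#'
#' @param session A filtered [monitoring_session()].
#' @param window_len Window length in minutes (>= 2).
#' @param stride Step between window starts (minutes).
#' @param locf_limit Maximum gap carried forward, minutes.
#' @param completeness_floor Minimum observed fraction for a usable window.
#' @return List of `window_matrix` objects (fields `session_id`,
#'   `start_minute`, `length`, `values`, `completeness`, `usable`).
#' @export
make_windows <- function(session, window_len = 15, stride = 1,
                         locf_limit = 5, completeness_floor = 0.8) {
  if (window_len < 2) stopf("window_len must be at least 2")
  if (is.null(session$validity))
    stopf("session must be filtered first (see filter_session)")
  grid <- session_grid(session)
  T_int <- nrow(grid)
  if (T_int < window_len) return(list())
  observed <- !is.na(grid)
  filled <- apply(grid, 2, locf_limited, limit = locf_limit)
  starts <- seq(1L, T_int - window_len + 1L, by = stride)
  lapply(starts, function(s0) {
    idx <- s0:(s0 + window_len - 1L)
    vals <- filled[idx, , drop = FALSE]
    comp <- mean(observed[idx, ])
    structure(list(session_id = session$session_id,
                   start_minute = session$intended_start + s0 - 1L,
                   length = window_len,
                   channels = CHANNELS,
                   values = vals,
                   completeness = comp,
                   usable = comp >= completeness_floor && !anyNA(vals)),
              class = "window_matrix")
  })
}

# Build a window_matrix directly from a value matrix (internal; used by the
# per-minute scorer and tests).
window_from_values <- function(values, session_id = "window", start_minute = 0,
                               completeness = 1) {
  structure(list(session_id = session_id, start_minute = start_minute,
                 length = nrow(values), channels = CHANNELS,
                 values = values, completeness = completeness,
                 usable = !anyNA(values)),
            class = "window_matrix")
}

#' Standardize a window with frozen channel statistics
#'
#' @param window A `window_matrix`.
#' @param stats Output of [channel_stats()].
#' @return The window with z-scored values.
#' @export
standardize_window <- function(window, stats) {
  window$values <- sweep(sweep(window$values, 2, stats$mean[CHANNELS]), 2,
                         stats$sd[CHANNELS], "/")
  window
}

#' Singular-vector signal conditioning
#'
#' Replaces the window by its best rank-`k` approximation (truncated SVD,
#' optimal in the least-squares sense), discarding the smallest-variance
#' directions that carry unphysical high-frequency events. The discarded
#' energy is `1 - sum(d[1:k]^2) / sum(d^2)` over the singular values `d`.
#' An (effectively) constant window is passed through unchanged with zero
#' discarded energy.
#'
#' @param window A standardized `window_matrix`.
#' @param rank Retained rank `k` (capped at `min(length, 3)`).
#' @return A `feature_vector`: fields `window` (reference), `values`
#'   (conditioned matrix), `rank`, `discarded_energy`.
#' @export
svd_condition <- function(window, rank = 2) {
  X <- window$values
  k <- min(rank, dim(X))
  sv <- La.svd(X)
  tot <- sum(sv$d^2)
  if (tot < 1e-12) {
    # rank-0 guard: constant/zero window passes through
    return(structure(list(window = window, values = X, rank = 0L,
                          discarded_energy = 0),
                     class = "feature_vector"))
  }
  Xk <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * sv$vt[seq_len(k), , drop = FALSE])
  dimnames(Xk) <- dimnames(X)
  structure(list(window = window, values = Xk, rank = as.integer(k),
                 discarded_energy = 1 - sum(sv$d[seq_len(k)]^2) / tot),
            class = "feature_vector")
}
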