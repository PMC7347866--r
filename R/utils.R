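#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so seeded helpers do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Nearest-rank empirical percentile (type 1), used for alarm calibration.
nearest_rank <- function(x, percentile) {
  x <- sort(x)
  n <- length(x)
  x[max(1L, ceiling(percentile / 100 * n))]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

CHANNELS <- c("hr", "rr", "spo2")
ALL_CHANNELS <- c("hr", "rr", "spo2", "pr")
SENSORS <- list(chest_ecg = c("hr", "rr"), pulse_ox = c("spo2", "pr"))
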