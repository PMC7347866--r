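# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small trained surprise-index model over stable synthetic sessions.
tiny_model <- function() {
  memo("tiny_model", {
    cohort <- generate_cohort(32, 0, seed = 3, duration_minutes = 480)
    cfg <- rapid_config(max_models = 80, model_stride = 30,
                        ns_max_iter = 300)
    suppressWarnings(train_rapid_model(cohort$sessions, cfg, seed = 1))
  })
}

# Hand-built dynamics model (for closed-form dissimilarity checks).
manual_model <- function(A, intercept, Sigma) {
  if (!is.list(A)) A <- list(A)
  structure(list(A = A, intercept = intercept, Sigma = Sigma,
                 order = length(A), channels = c("hr", "rr", "spo2"),
                 source = list(session_id = "manual", start_minute = 0)),
            class = "dynamics_model")
}

random_feature <- function(n = 15, seed = 1, sd = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 3, sd = sd), n, 3,
                 dimnames = list(NULL, c("hr", "rr", "spo2")))
  rapidindex:::window_from_values(vals)
}

# Fully captured, artifact-free session with prescribed channel values.
plain_session <- function(values, id = "plain") {
  df <- data.frame(minute = seq_len(nrow(values)) - 1,
                   hr = values[, 1], rr = values[, 2], spo2 = values[, 3],
                   pr = values[, 1])
  filter_session(monitoring_session(id, 24, df, intended_end = nrow(values)))
}

sammon_stress <- function(Y, D) {
  dy <- as.matrix(dist(Y))
  sum(((D - dy)[upper.tri(D)])^2)
}

# Brute-force metric MDS stress: unconstrained minimisation over the 2-D
# configuration, multi-started. Independent oracle for projection training.
mds_stress_oracle <- function(D, n_starts = 4, seed = 1) {
  n <- nrow(D)
  obj <- function(y) sammon_stress(matrix(y, n, 2), D)
  inits <- list(as.numeric(cmdscale(D, k = 2)))
  set.seed(seed)
  for (i in seq_len(n_starts - 1))
    inits[[i + 1]] <- inits[[1]] + rnorm(2 * n, sd = 0.1 * sd(inits[[1]]))
  min(vapply(inits, function(y0)
    optim(y0, obj, method = "BFGS",
          control = list(maxit = 3000, reltol = 1e-12))$value, numeric(1)))
}
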