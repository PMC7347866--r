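test_that("threshold calibration is the nearest-rank percentile", {
  expect_equal(calibrate_threshold(1:100, 95), 95)
  expect_equal(calibrate_threshold(sample(1:100), 95), 95)
  expect_equal(calibrate_threshold(rep(7, 200), 95), 7)
  expect_error(calibrate_threshold(1:99), "100")
})

test_that("alarm extraction finds maximal super-threshold runs", {
  series <- function(idx) data.frame(minute = seq_along(idx) - 1, index = idx)
  expect_equal(nrow(generate_alerts(series(rep(0.1, 30)), threshold = 1)), 0)

  spike <- rep(0, 30); spike[11] <- 5
  a <- generate_alerts(series(spike), threshold = 1)
  expect_equal(a$start_minute, 10)
  expect_equal(a$end_minute, 10)
  expect_equal(a$peak_index, 5)

  square <- rep(c(0, 2, 0, 2, 0), times = c(5, 4, 5, 6, 5))
  a2 <- generate_alerts(series(square), threshold = 1)
  expect_equal(nrow(a2), 2)
  expect_equal(a2$start_minute, c(5, 14))
  expect_equal(a2$end_minute, c(8, 19))
})

test_that("alarm durations conserve the count of super-threshold minutes", {
  set.seed(31)
  for (i in 1:5) {
    idx <- pmax(rnorm(500), 0)
    thr <- quantile(idx, 0.9)
    a <- generate_alerts(data.frame(minute = 0:499, index = idx),
                         threshold = thr)
    expect_equal(sum(a$end_minute - a$start_minute + 1), sum(idx >= thr))
  }
})

test_that("phenotype clustering finds well-separated groups", {
  set.seed(32)
  Y <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  phen <- fit_phenotypes(Y, k_range = 2:6, seed = 1)
  expect_equal(phen$k, 2)
  cent <- phen$centroids[order(phen$centroids[, 1]), ]
  expect_equal(cent[1, ], c(0, 0), tolerance = 0.3, ignore_attr = TRUE)
  expect_equal(cent[2, ], c(5, 5), tolerance = 0.3, ignore_attr = TRUE)
  # assignments are consistent within blobs (labels arbitrary)
  expect_length(unique(phen$assignment[1:20]), 1)
  expect_length(unique(phen$assignment[21:40]), 1)
  expect_false(phen$assignment[1] == phen$assignment[21])

  expect_warning(p1 <- fit_phenotypes(matrix(1, 10, 2), seed = 1), "single")
  expect_equal(p1$k, 1)
})

zero_var_phenotype <- function(mean = c(100, 25, 97)) {
  structure(list(centroids = matrix(0, 1, 2), k = 1L,
                 channel_stats = list(list(mean = mean, sd = c(0, 0, 0),
                                           phi = c(0, 0, 0)))),
            class = "phenotype_model")
}

test_that("imputation honours the 15-minute limit and the phenotype model", {
  T <- 60
  vals <- matrix(rep(c(110, 24, 96), each = T), T, 3)
  mk_gap <- function(gap_at) {
    df <- data.frame(minute = 0:(T - 1), hr = vals[, 1], rr = vals[, 2],
                     spo2 = vals[, 3], pr = vals[, 1])
    df$spo2[gap_at + 1] <- NA
    filter_session(monitoring_session("gap", 24, df, intended_end = T))
  }
  phen <- zero_var_phenotype()

  # 16-minute gap is refused outright
  long <- mk_gap(20:35)
  out <- impute_missing(long, phen, phenotype_id = 1, limit = 15)
  expect_true(all(is.na(out$values[21:36, "spo2"])))
  expect_false(any(out$imputed))

  # 1-minute gap: zero-variance phenotype imputes the phenotype mean exactly
  short <- mk_gap(20)
  out2 <- impute_missing(short, phen, phenotype_id = 1, limit = 15)
  expect_equal(unname(out2$values[21, "spo2"]), 97)
  expect_true(out2$imputed[21, "spo2"])
  expect_equal(sum(out2$imputed), 1)

  # no phenotype assigned: carry-forward
  out3 <- impute_missing(short, phen, phenotype_id = NA, limit = 15)
  expect_equal(unname(out3$values[21, "spo2"]), 96)
})

test_that("imputed values from a live phenotype stay in a plausible range", {
  model <- tiny_model()
  phen <- model$phenotypes
  T <- 60
  set.seed(33)
  vals <- cbind(rnorm(T, 115, 3), rnorm(T, 28, 2), rnorm(T, 97, 1))
  df <- data.frame(minute = 0:(T - 1), hr = vals[, 1], rr = vals[, 2],
                   spo2 = vals[, 3], pr = vals[, 1])
  df$hr[31] <- NA
  s <- filter_session(monitoring_session("imp", 24, df, intended_end = T))
  out <- impute_missing(s, phen, phenotype_id = 1, limit = 15)
  ps <- phen$channel_stats[[1]]
  expect_true(out$imputed[31, "hr"])
  expect_lt(abs(out$values[31, "hr"] - ps$mean[1]), 4 * max(ps$sd[1], 10))
})

test_that("constant vitals give an essentially constant index", {
  model <- tiny_model()
  T <- 120
  s <- plain_session(matrix(rep(c(115, 28, 97), each = T), T, 3), "const")
  idx <- compute_rapid_index(s, model)
  vals <- idx$data$index[idx$data$minute >= 20]
  expect_true(all(!is.na(vals)))
  expect_lt(sd(vals), 1e-6)
})

test_that("the index stays available through a short single-sensor outage", {
  model <- tiny_model()
  sc <- synthetic_scenario(24, 240, dropout_rate = c(chest_ecg = 0, pulse_ox = 0),
                           artifact_rate = 0, seed = 77)
  s <- generate_session(sc, "outage")
  s$samples$spo2[101:111] <- NA  # pulse oximeter silent for 11 minutes
  s$samples$pr[101:111] <- NA
  s <- filter_session(s)
  idx <- compute_rapid_index(s, model)
  span <- idx$data[idx$data$minute %in% 100:110, ]
  expect_true(all(!is.na(span$index)))
  expect_true(all(span$flag == "imputed"))

  # a gap beyond the limit makes the index unavailable instead
  s2 <- generate_session(sc, "outage2")
  s2$samples$spo2[101:140] <- NA
  s2$samples$pr[101:140] <- NA
  s2 <- filter_session(s2)
  idx2 <- compute_rapid_index(s2, model)
  expect_true(any(idx2$data$flag == "unavailable"))
})

test_that("warm-up scoring starts at minute five", {
  model <- tiny_model()
  s <- generate_session(synthetic_scenario(24, 60, seed = 41,
                                           dropout_rate = c(chest_ecg = 0, pulse_ox = 0),
                                           artifact_rate = 0), "warm")
  idx <- compute_rapid_index(s, model)
  expect_true(all(is.na(idx$data$index[idx$data$minute < 5])))
  expect_true(all(idx$data$flag[idx$data$minute < 5] == "warmup"))
  expect_false(is.na(idx$data$index[idx$data$minute == 5]))
})

test_that("a replayed training session scores typically below the alarm threshold", {
  model <- tiny_model()
  cohort <- generate_cohort(32, 0, seed = 3, duration_minutes = 480)
  idx <- compute_rapid_index(cohort$sessions[[1]], model)
  expect_lt(median(idx$data$index, na.rm = TRUE), model$threshold)
})
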