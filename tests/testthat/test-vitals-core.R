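test_that("validity flags follow the exclusive range bounds per channel", {
  cfg <- validity_config()
  # exhaustive boundary sweep: below-min invalid, at-min valid, at-max valid,
  # above-max invalid
  boundary <- list(hr = c(19, 20, 300, 301), pr = c(19, 20, 300, 301),
                   rr = c(4, 5, 200, 201))
  for (ch in names(boundary)) {
    vals <- boundary[[ch]]
    got <- vapply(vals, function(v) {
      s <- setNames(list(v), ch)
      validate_sample(s, cfg)[[ch]]
    }, character(1))
    expect_equal(got, c("invalid", "valid", "valid", "invalid"),
                 info = ch)
  }
  expect_equal(validate_sample(list(spo2 = 29), cfg)[["spo2"]], "invalid")
  expect_equal(validate_sample(list(spo2 = 30), cfg)[["spo2"]], "valid")
  # mid-range all valid, absent channels missing
  flags <- validate_sample(list(hr = 120, rr = 25, spo2 = 98), cfg)
  expect_equal(unname(flags[c("hr", "rr", "spo2")]), rep("valid", 3))
  expect_equal(flags[["pr"]], "missing")
})

test_that("quality report arithmetic is exact on constructed sessions", {
  df <- data.frame(minute = 0:99, hr = c(rep(10, 10), rep(120, 90)),
                   rr = 25, spo2 = 98, pr = 120)
  s <- filter_session(monitoring_session("a", 24, df, intended_end = 100))
  expect_equal(s$quality$valid_minutes[["chest_ecg"]], 90)
  expect_equal(s$quality$proportion_valid[["chest_ecg"]], 0.9)
  expect_equal(s$quality$proportion_captured[["chest_ecg"]], 1)

  df2 <- data.frame(minute = 0:99, hr = 120, rr = 25,
                    spo2 = NA_real_, pr = NA_real_)
  s2 <- filter_session(monitoring_session("b", 24, df2, intended_end = 100))
  expect_equal(s2$quality$proportion_captured[["pulse_ox"]], 0)
  expect_equal(s2$quality$valid_minutes[["pulse_ox"]], 0)

  empty <- monitoring_session("c", 1, data.frame(minute = numeric(0)),
                              intended_end = 10)
  expect_error(filter_session(empty), "no samples")
})

test_that("filtering is idempotent, conserves minutes and is monotone in the ranges", {
  wide <- validity_config(hr_min = 1, hr_max = 1000, rr_min = 1,
                          rr_max = 1000, spo2_min = 1)
  for (seed in 1:4) {
    s <- generate_session(synthetic_scenario(duration_minutes = 300,
                                             seed = seed,
                                             artifact_rate = 0.1))
    f <- filter_session(s)
    expect_identical(filter_session(f)$validity, f$validity)
    q <- f$quality
    for (sensor in c("chest_ecg", "pulse_ox")) {
      captured <- q$captured_minutes[[sensor]]
      valid <- q$valid_minutes[[sensor]]
      missing <- q$intended_minutes - captured
      expect_true(0 <= valid && valid <= captured &&
                    captured <= q$intended_minutes)
      expect_equal(missing + (captured - valid) + valid, q$intended_minutes)
    }
    fw <- filter_session(s, wide)
    expect_true(all(fw$quality$valid_minutes >= q$valid_minutes))
  }
})

test_that("filtering recovers the injected artifact count exactly", {
  s <- generate_session(synthetic_scenario(duration_minutes = 2000,
                                           seed = 11, artifact_rate = 0.05))
  f <- filter_session(s)
  art <- attr(s, "injected_artifacts")
  for (sensor in c("chest_ecg", "pulse_ox")) {
    k <- sum(art$sensor == sensor)
    invalid <- f$quality$captured_minutes[[sensor]] -
      f$quality$valid_minutes[[sensor]]
    expect_equal(invalid, k, info = sensor)
  }
})

test_that("sessions round-trip through CSV and JSON with all fields", {
  s <- generate_session(synthetic_scenario(
    duration_minutes = 60, seed = 2,
    deterioration = list(onset_minute = 10, event_minute = 50)), "rt")
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_session(s, csv)
  write_session(s, js)
  for (s2 in list(read_session(csv), read_session(js))) {
    expect_equal(s2$samples, s$samples)
    expect_equal(s2$session_id, s$session_id)
    expect_equal(s2$patient_age_months, s$patient_age_months)
    expect_equal(s2$intended_end, s$intended_end)
    expect_equal(s2$annotations$onset_minute, 10)
    expect_equal(s2$annotations$event_type, s$annotations$event_type)
  }
})

test_that("CSV reading normalises and validates its input", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("# session_id: x", "# intended_end: 3",
               "minute,hr,rr,spo2,pr", "2,100,20,97,100",
               "0,110,22,98,110", "1,105,21,97,105"), p)
  expect_warning(s <- read_session(p), "not monotone")
  expect_equal(s$samples$minute, 0:2)
  expect_equal(s$samples$hr, c(110, 105, 100))

  writeLines(c("minute,hr,rr,pr", "0,100,20,100", "1,101,21,101"), p)
  s <- read_session(p)
  expect_true(all(is.na(s$samples$spo2)))

  writeLines(c("minute,hr,rr,spo2,pr,junk", "0,100,20,97,100,9"), p)
  expect_warning(read_session(p), "unknown column")

  writeLines(c("minute,hr,rr,spo2,pr", "0,100,20,97,100", "1,oops,20,97,100"), p)
  expect_error(read_session(p), "row 2")
})

test_that("duplicate minutes keep the last value with a warning", {
  df <- data.frame(minute = c(0, 1, 1, 2), hr = c(100, 101, 150, 102),
                   rr = 20, spo2 = 97, pr = 100)
  expect_warning(s <- monitoring_session("d", 12, df, intended_end = 3),
                 "duplicate")
  expect_equal(s$samples$hr, c(100, 150, 102))
})
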