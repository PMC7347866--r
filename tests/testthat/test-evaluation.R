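alert_row <- function(id, minute) data.frame(session_id = id,
                                             start_minute = minute,
                                             end_minute = minute)
no_alerts <- alert_row("x", 0)[0, ]

test_that("session classification reproduces the study-scale table", {
  case_ids <- sprintf("case%02d", 1:36)
  control_ids <- sprintf("ctrl%02d", 1:36)
  events <- data.frame(session_id = case_ids, event_minute = 6000)
  # 35 cases alert inside the 72 h window, 27 controls alert at some point
  case_alerts <- do.call(rbind, lapply(case_ids[1:35], alert_row, minute = 5000))
  control_alerts <- do.call(rbind, lapply(control_ids[1:27], alert_row,
                                          minute = 100))
  tab <- classify_sessions(case_alerts, control_alerts, events, control_ids,
                           evaluation_config(detection_window_hours = 72))
  expect_equal(unlist(tab[c("tp", "fn", "fp", "tn")]),
               c(tp = 35, fn = 1, fp = 27, tn = 9))

  none <- classify_sessions(no_alerts, no_alerts, events, control_ids)
  expect_equal(unlist(none[c("tp", "fn", "fp", "tn")]),
               c(tp = 0, fn = 36, fp = 0, tn = 36))

  # an alert before the window does not count for the case
  early <- alert_row("case01", 6000 - 72 * 60 - 1)
  tab2 <- classify_sessions(early, no_alerts, events[1, , drop = FALSE],
                            character(0),
                            evaluation_config(detection_window_hours = 72))
  expect_equal(tab2$tp, 0)
  expect_error(classify_sessions(no_alerts, no_alerts,
                                 data.frame(session_id = "a",
                                            event_minute = NA),
                                 character(0)), "event time")
})

test_that("vectorised classification agrees with a naive per-session loop", {
  set.seed(60)
  cfg <- evaluation_config(detection_window_hours = 24)
  for (i in 1:5) {
    n_case <- sample(5:12, 1); n_ctrl <- sample(5:12, 1)
    case_ids <- sprintf("c%02d", seq_len(n_case))
    control_ids <- sprintf("k%02d", seq_len(n_ctrl))
    events <- data.frame(session_id = case_ids,
                         event_minute = sample(2000:4000, n_case))
    rand_alerts <- function(ids) do.call(rbind, c(list(no_alerts),
      lapply(ids, function(id) {
        k <- sample(0:3, 1)
        if (k == 0) return(NULL)
        st <- sort(sample(0:4000, k))
        data.frame(session_id = id, start_minute = st, end_minute = st + 5)
      })))
    ca <- rand_alerts(case_ids); ka <- rand_alerts(control_ids)
    tab <- classify_sessions(ca, ka, events, control_ids, cfg)
    # oracle: explicit loop over sessions and alerts
    w <- 24 * 60
    tp <- 0
    for (j in seq_len(n_case)) {
      a <- ca[ca$session_id == case_ids[j], ]
      ev <- events$event_minute[j]
      hit <- FALSE
      for (r in seq_len(nrow(a)))
        if (a$end_minute[r] >= ev - w && a$start_minute[r] <= ev) hit <- TRUE
      tp <- tp + hit
    }
    fp <- sum(vapply(control_ids, function(id)
      any(ka$session_id == id), logical(1)))
    expect_equal(tab$tp, tp)
    expect_equal(tab$fp, fp)
  }
})

test_that("accuracy estimates reproduce the exact binomial arithmetic", {
  # 31/36 sensitivity, 29/36 specificity, prevalence 5.6%
  acc <- accuracy(contingency_table(31, 5, 7, 29))
  expect_equal(100 * acc$sensitivity$estimate, 86.1, tolerance = 5e-4)
  expect_equal(round(100 * acc$sensitivity$ci, 1), c(70.5, 95.3),
               ignore_attr = TRUE)
  expect_equal(round(100 * acc$specificity$estimate, 1), 80.6)
  expect_equal(round(100 * acc$specificity$ci, 1), c(64.0, 91.8),
               ignore_attr = TRUE)
  expect_equal(round(100 * acc$ppv$estimate, 1), 20.8)
  expect_equal(round(100 * acc$npv$estimate, 1), 99.0)

  acc2 <- accuracy(contingency_table(35, 1, 27, 9))
  expect_equal(round(100 * acc2$ppv$estimate, 1), 7.1)
  expect_equal(round(100 * acc2$npv$estimate, 1), 99.3)
  expect_equal(round(100 * acc2$specificity$estimate, 1), 25.0)

  expect_error(accuracy(contingency_table(0, 0, 5, 5)), "sensitivity")
  expect_error(accuracy(contingency_table(5, 5, 0, 0)), "specificity")
})

test_that("predictive values approach their prevalence limits and are monotone", {
  tab <- contingency_table(31, 5, 7, 29)
  hi <- accuracy(tab, evaluation_config(prevalence = 0.999))
  lo <- accuracy(tab, evaluation_config(prevalence = 0.001))
  expect_gt(hi$ppv$estimate, 0.99)
  expect_gt(lo$npv$estimate, 0.99)
  grid <- seq(0.01, 0.99, by = 0.07)
  ppv <- vapply(grid, function(p)
    accuracy(tab, evaluation_config(prevalence = p))$ppv$estimate, numeric(1))
  npv <- vapply(grid, function(p)
    accuracy(tab, evaluation_config(prevalence = p))$npv$estimate, numeric(1))
  expect_true(all(diff(ppv) > 0))
  expect_true(all(diff(npv) < 0))
})

test_that("intervals contain their estimates and tighten with sample size", {
  a1 <- accuracy(contingency_table(8, 2, 3, 7))
  a2 <- accuracy(contingency_table(16, 4, 6, 14))
  for (comp in c("sensitivity", "specificity", "ppv", "npv")) {
    e1 <- a1[[comp]]
    expect_true(e1$ci[1] <= e1$estimate && e1$estimate <= e1$ci[2])
    expect_lt(diff(a2[[comp]]$ci), diff(a1[[comp]]$ci))
  }
})

test_that("paired comparison recovers the printed differences and McNemar forms", {
  # method A identifies 31/36 cases, method B 35/36 (B superset of A)
  a <- rep(c(TRUE, FALSE), c(31, 5))
  b <- rep(c(TRUE, FALSE), c(35, 1))
  ctrl_a <- rep(c(TRUE, FALSE), c(7, 29))   # specificity 29/36
  ctrl_b <- rep(c(TRUE, FALSE), c(27, 9))   # specificity 9/36
  cmp <- compare_paired(a, b, ctrl_a, ctrl_b)
  expect_equal(100 * cmp$sensitivity$difference, 11.1, tolerance = 5e-3)
  expect_equal(100 * abs(cmp$specificity$difference), 55.6, tolerance = 5e-3)

  same <- compare_paired(a, a, ctrl_a, ctrl_a)
  expect_equal(same$sensitivity$difference, 0)
  expect_equal(same$sensitivity$p_value, 1)

  # discordant pairs (10, 0): exact two-sided binomial p = 2 * (1/2)^10
  x <- rep(TRUE, 20)
  y <- rep(c(FALSE, TRUE), c(10, 10))
  cmp2 <- compare_paired(x, y, ctrl_a, ctrl_a)
  expect_equal(cmp2$sensitivity$p_value, 2 * 0.5^10)
  expect_equal(cmp2$sensitivity$method, "exact")

  # 25+ discordant pairs: continuity-corrected chi-square matches stats::
  x2 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 20, 10, 10))
  y2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 20, 10, 10))
  cmp3 <- compare_paired(x2, y2, ctrl_a, ctrl_a)
  oracle <- mcnemar.test(table(x2, y2), correct = TRUE)
  expect_equal(cmp3$sensitivity$p_value, oracle$p.value)
  expect_equal(cmp3$sensitivity$method, "chi-square")
  expect_error(compare_paired(a, a[-1], ctrl_a, ctrl_a), "equal length")
})

test_that("warning-time summaries recompute the printed arithmetic", {
  times <- c(rep(30, 13), 64.9)  # totals 454.9 h over 14 events
  ids <- sprintf("e%02d", 1:14)
  events <- data.frame(session_id = ids, event_minute = 6000)
  alerts <- do.call(rbind, lapply(seq_along(ids), function(i)
    alert_row(ids[i], 6000 - times[i] * 60)))
  wt <- warning_times(alerts, events, evaluation_config(72))
  expect_equal(wt$n, 14)
  expect_equal(wt$total, 454.9)
  expect_equal(wt$mean, 454.9 / 14)

  # single event alerted exactly at the event
  wt0 <- warning_times(alert_row("e01", 6000), events[1, , drop = FALSE])
  expect_equal(c(wt0$mean, wt0$min, wt0$max), c(0, 0, 0))

  # events never alerted are excluded and n reflects it
  wt2 <- warning_times(alerts[-1, ], events)
  expect_equal(wt2$n, 13)

  # summary agrees with a brute-force recompute on random samples
  set.seed(61)
  x <- runif(20, 0, 80)
  ws <- warning_time_summary(x)
  expect_equal(ws$mean, sum(x) / 20)
  expect_equal(c(ws$q1, ws$median, ws$q3),
               unname(quantile(x, c(.25, .5, .75))))
  expect_true(ws$min <= ws$q1 && ws$q1 <= ws$median &&
                ws$median <= ws$q3 && ws$q3 <= ws$max)
})

test_that("constructed cohorts round-trip through classification and accuracy", {
  # build a cohort whose detection pattern is known exactly
  case_ids <- sprintf("c%02d", 1:10)
  control_ids <- sprintf("k%02d", 1:8)
  events <- data.frame(session_id = case_ids, event_minute = 3000)
  detected <- case_ids[1:7]
  fp_ids <- control_ids[1:2]
  ca <- do.call(rbind, lapply(detected, alert_row, minute = 2950))
  ka <- do.call(rbind, lapply(fp_ids, alert_row, minute = 10))
  acc <- accuracy(classify_sessions(ca, ka, events, control_ids,
                                    evaluation_config(24)),
                  evaluation_config(24))
  expect_equal(acc$sensitivity$estimate, 7 / 10)
  expect_equal(acc$specificity$estimate, 6 / 8)
})
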