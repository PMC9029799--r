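test_that("settings grid enumeration yields the canonical counts", {
  full <- enumerate_settings(2, 30)
  expect_equal(nrow(full), 435)
  expect_equal(nrow(enumerate_settings(2, 2)), 1)
  expect_equal(enumerate_settings(2, 2)$window_threshold, 1)
  expect_equal(nrow(enumerate_settings(2, 5)), 10)  # 1+2+3+4
  # lexicographic order, threshold always below length
  expect_true(all(full$window_threshold < full$window_length))
  expect_true(!is.unsorted(full$window_length))
  expect_error(enumerate_settings(1, 5), "min_len")
})

test_that("settings validation enforces the parameter ranges", {
  expect_error(algorithm_settings("static", 31, 5), "window_length")
  expect_error(algorithm_settings("static", 5, 5), "window_threshold")
  expect_error(algorithm_settings("static", 5, 0), "window_threshold")
  expect_error(algorithm_settings("static", 5, 2, decrease_mult = 0),
               "decrease_mult")
})

test_that("expected RMSSD is the calibration line, with intercept swap for dynamic", {
  s <- make_linear_series(intercept = 50, slope = -2,
                          aee = seq(0.1, 5, length.out = 50))
  m <- fit_calibration(s)
  expect_equal(expected_rmssd(m, 3), 44)
  expect_equal(expected_rmssd(m, 0), m$intercept)
  expect_equal(expected_rmssd(m, c(1, 2), dynamic_intercept = m$intercept),
               expected_rmssd(m, c(1, 2)))
})

test_that("decrease flags implement the threshold inequality exactly", {
  m <- fit_calibration(make_linear_series(intercept = 50, slope = 0,
                                          aee = runif(50, 0.1, 2),
                                          noise = 4, seed = 2))
  st <- algorithm_settings("static", 5, 3)
  margin <- st$decrease_mult * m$sd_rmssd_cal

  high <- participant_series("p", rep(m$intercept + 10 * m$sd_rmssd_cal, 20),
                             rep(1, 20))
  high$participant_id <- m$participant_id
  expect_equal(sum(flag_decreases(high, m, st)$decrease_flags), 0)

  low <- participant_series("p", rep(m$intercept - 10 * m$sd_rmssd_cal, 20),
                            rep(1, 20))
  low$participant_id <- m$participant_id
  expect_equal(sum(flag_decreases(low, m, st)$decrease_flags), 20)

  # 10-minute series with 3 planted sub-threshold minutes
  rm10 <- rep(m$intercept, 10)
  rm10[c(3, 6, 9)] <- m$intercept - margin - 1
  ten <- participant_series(m$participant_id, rm10, rep(0, 10))
  fl <- flag_decreases(ten, m, st)
  expect_identical(which(fl$decrease_flags), c(3L, 6L, 9L))
  expect_equal(fl$threshold_trace,
               expected_rmssd(m, rep(0, 10)) - margin)

  # invalid minutes are never flagged
  ten$data$valid[3] <- FALSE
  expect_identical(which(flag_decreases(ten, m, st)$decrease_flags),
                   c(6L, 9L))
})

test_that("dynamic intercept has the fixed point and branch behavior", {
  s <- make_linear_series(n = 200, intercept = 50, slope = -6,
                          aee = runif(200, 0.1, 2), seed = 3)
  m <- fit_calibration(s)
  st <- algorithm_settings("dynamic", 6, 4)

  # RMSSD pinned at the intercept, AEE below calibration mean: fixed point
  fx <- participant_series(m$participant_id, rep(m$intercept, 150),
                           rep(0, 150))
  expect_equal(run_dynamic_state(fx, m, st), rep(m$intercept, 150))

  # AEE permanently above the calibration mean: buffer never absorbs HRV
  hot <- participant_series(m$participant_id, runif(150, 20, 90),
                            rep(m$mean_aee_cal + 5, 150))
  expect_equal(run_dynamic_state(hot, m, st), rep(m$intercept, 150))
})

test_that("a step change in RMSSD ramps the dynamic intercept linearly over 60 min", {
  s <- make_linear_series(n = 200, intercept = 50, slope = -6,
                          aee = runif(200, 0.5, 2), seed = 4)
  m <- fit_calibration(s)
  m$intercept <- 50  # exact closed-form construction
  st <- algorithm_settings("dynamic", 6, 4)
  n <- 200
  step_at <- 100L  # 0-based minute of the step
  rmssd <- c(rep(50, step_at), rep(70, n - step_at))
  x <- participant_series(m$participant_id, rmssd, rep(0, n))
  dyn <- run_dynamic_state(x, m, st)
  j <- 0:60
  expect_equal(dyn[step_at + 1 + j], 50 + j * 20 / 60, tolerance = 1e-12)
  expect_equal(dyn[(step_at + 62):n], rep(70, n - step_at - 61))
  expect_equal(dyn[1:(step_at + 1)], rep(50, step_at + 1))
})

test_that("streaming trigger scan equals the naive re-scan oracle", {
  set.seed(77)
  for (k in 1:300) {
    n <- sample(10:300, 1)
    flags <- runif(n) < runif(1, 0.05, 0.6)
    L <- sample(2:30, 1)
    K <- sample(seq_len(L - 1), 1)
    silent <- sample(0:40, 1)
    got <- addhrvr:::scan_triggers(flags, L, K, silent)
    want <- naive_trigger_oracle(flags, L, K, silent)
    expect_identical(got, want)
  }
})

test_that("saturated flags with 1-out-of-2 and silent 20 trigger at minutes 1, 22, 43, ...", {
  got <- addhrvr:::scan_triggers(rep(TRUE, 100), 2, 1, 20)
  expect_identical(got, seq(1L, 99L, by = 21L))
  expect_identical(addhrvr:::scan_triggers(rep(FALSE, 100), 2, 1, 20),
                   integer(0))
})

test_that("run_algorithm is causal and respects the silent spacing", {
  co <- small_cohort(n = 3, seed = 12, duration = 400)
  models <- cohort_calibrations(co, screen = FALSE)
  st <- algorithm_settings("static", 5, 3, silent_min = 15)
  for (i in 1:3) {
    train <- run_algorithm(co$series[[i]], models[[i]], st)
    if (length(train$trigger_minutes) > 1) {
      expect_true(all(diff(train$trigger_minutes) > 15))
    }
    # truncation never changes earlier triggers
    s <- co$series[[i]]
    cut <- 200L
    s2 <- participant_series(s$participant_id, s$data$rmssd[1:cut],
                             s$data$aee[1:cut], valid = s$data$valid[1:cut])
    t2 <- run_algorithm(s2, models[[i]], st)
    expect_identical(t2$trigger_minutes,
                     train$trigger_minutes[train$trigger_minutes < cut])
  }
})

test_that("pre-silencing k-of-n minutes are monotone in the threshold", {
  set.seed(99)
  flags <- runif(300) < 0.3
  for (L in c(5, 12)) {
    prev <- NULL
    for (K in seq_len(L - 1)) {
      cur <- addhrvr:::scan_triggers(flags, L, K, silent_min = 0)
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("static and dynamic variants diverge on a drifting series", {
  set.seed(55)
  n <- 720
  aee <- pmax(0, 0.6 + rnorm(n, 0, 0.2))
  drift <- 25 * sin(2 * pi * (1:n) / 720)  # slow HRV level drift
  rmssd <- 55 - 6 * aee + drift + rnorm(n, 0, 6)
  s <- participant_series("p", rmssd, aee)
  m <- fit_calibration(s)
  st_s <- algorithm_settings("static", 6, 4)
  st_d <- algorithm_settings("dynamic", 6, 4)
  tr_s <- run_algorithm(s, m, st_s)
  tr_d <- run_algorithm(s, m, st_d)
  expect_false(identical(tr_s$trigger_minutes, tr_d$trigger_minutes))
})

test_that("variant/model-kind mismatches are refused", {
  s <- make_linear_series(n = 60, seed = 6)
  lin <- fit_calibration(s)
  inv <- fit_calibration(s, predictor_kind = "inverse")
  expect_error(run_algorithm(s, lin, algorithm_settings("inverse", 5, 3)),
               "inverse-kind")
  expect_error(run_algorithm(s, inv, algorithm_settings("dynamic", 5, 3)),
               "linear-kind")
  expect_error(run_dynamic_state(s, inv, algorithm_settings("dynamic", 5, 3)),
               "linear-kind")
})

test_that("trigger trains export per-minute tables", {
  s <- make_linear_series(n = 60, noise = 8, seed = 7)
  m <- fit_calibration(s)
  train <- run_algorithm(s, m, algorithm_settings("static", 4, 2))
  tab <- trigger_train_table(train)
  expect_equal(nrow(tab), 60)
  expect_equal(sum(tab$trigger), length(train$trigger_minutes))
  expect_equal(which(tab$decrease_flag == 1) - 1L,
               which(train$decrease_flags) - 1L)
})
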