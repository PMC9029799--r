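# build an event table from per-cell counts of the direction x trigger 2x2
events_from_2x2 <- function(n00, n01, n10, n11, n_participants = 4) {
  df <- data.frame(
    direction = c(rep(0L, n00 + n01), rep(1L, n10 + n11)),
    trigger_present = c(rep(0L, n00), rep(1L, n01), rep(0L, n10),
                        rep(1L, n11))
  )
  df$participant_id <- rep_len(sprintf("p%d", seq_len(n_participants)),
                               nrow(df))
  df
}

test_that("zero-variance fit equals the closed-form 2x2 cross-product ratio", {
  # strongly associated table: 46 of 182 increases vs 25 of 170 decreases
  ev <- events_from_2x2(n00 = 145, n01 = 25, n10 = 136, n11 = 46)
  fit <- fit_random_intercept_logistic(ev, constrain_zero_variance = TRUE)
  or_oracle <- (46 * 145) / (25 * 136)
  expect_true(fit$converged)
  expect_equal(fit$odds_ratio, or_oracle, tolerance = 1e-4)
})

test_that("single-participant grouping matches plain logistic regression", {
  set.seed(71)
  ev <- events_from_2x2(40, 20, 25, 35, n_participants = 1)
  fit <- fit_random_intercept_logistic(ev)
  ref <- glm(direction ~ trigger_present, family = binomial(), data = ev)
  expect_equal(fit$beta_trigger, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$p_value,
               summary(ref)$coefficients[2, 4], tolerance = 1e-6)
})

test_that("the mixed fit approaches the pooled fit when intercepts are homogeneous", {
  set.seed(72)
  ev <- events_from_2x2(120, 60, 80, 110, n_participants = 8)
  mixed <- fit_random_intercept_logistic(ev)
  pooled <- fit_random_intercept_logistic(ev, constrain_zero_variance = TRUE)
  expect_true(mixed$converged)
  # balanced assignment gives zero between-participant variance
  expect_equal(mixed$beta_trigger, pooled$beta_trigger, tolerance = 1e-3)
})

test_that("degenerate event sets are flagged, not raised", {
  all_inc <- events_from_2x2(0, 0, 10, 10)
  expect_false(fit_random_intercept_logistic(all_inc)$converged)
  no_trig <- events_from_2x2(10, 0, 10, 0)
  expect_false(fit_random_intercept_logistic(no_trig)$converged)
  separated <- events_from_2x2(10, 0, 0, 10)
  expect_false(fit_random_intercept_logistic(separated)$converged)
  expect_false(fit_random_intercept_logistic(all_inc[0, ])$converged)
})

test_that("a null association gives a near-zero coefficient", {
  set.seed(73)
  n <- 4000
  ev <- data.frame(
    participant_id = rep(sprintf("p%d", 1:20), each = n / 20),
    direction = rbinom(n, 1, 0.5),
    trigger_present = rbinom(n, 1, 0.4)
  )
  fit <- fit_random_intercept_logistic(ev)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta_trigger / fit$se), 3)
})

test_that("likelihood-ratio testing is available and agrees in order of magnitude", {
  set.seed(74)
  ev <- events_from_2x2(60, 30, 40, 55, n_participants = 6)
  wald <- fit_random_intercept_logistic(ev)
  lrt <- fit_random_intercept_logistic(ev, test = "lrt")
  expect_true(lrt$converged)
  expect_equal(log10(lrt$p_value), log10(wald$p_value), tolerance = 0.5)
})

test_that("bootstrap_setting is a pure function of cohort and seed", {
  co <- small_cohort(effect_drop = 12, n = 10, seed = 5, duration = 720)
  st <- algorithm_settings("static", 6, 3)
  a <- bootstrap_setting(co, st, iters = 30, seed = 99)
  b <- bootstrap_setting(co, st, iters = 30, seed = 99)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$mean_pct_odds && a$mean_pct_odds <= a$ci_high)
  expect_lte(a$n_valid_iters, 30)
})

test_that("a strongly planted effect yields high power and positive odds change", {
  co <- generate_cohort(generator_params(
    n_participants = 20, duration_min = 720, effect_drop = 25, seed = 6
  ))
  st <- algorithm_settings("dynamic", 10, 7)
  res <- bootstrap_setting(co, st, iters = 60, seed = 2)
  expect_gt(res$power, 0.9)
  expect_gt(res$mean_pct_odds, 0)
  expect_false(res$unreliable)
})

test_that("sweep_grid covers the restricted grid and orders by power", {
  co <- small_cohort(effect_drop = 15, n = 8, seed = 7, duration = 480)
  res <- sweep_grid(co, "static", min_len = 2, max_len = 5, iters = 15,
                    seed = 3)
  expect_equal(nrow(res), 10)
  expect_true(!is.unsorted(rev(res$power), na.rm = TRUE))
  expect_equal(nrow(attr(res, "grid")), 10)
  # same cohort and seed, second variant: independent 10-row table
  res_d <- sweep_grid(co, "dynamic", min_len = 2, max_len = 5, iters = 15,
                      seed = 3)
  expect_equal(nrow(res_d), 10)
})

test_that("power_curve reports threshold crossings consistently", {
  co <- small_cohort(effect_drop = 20, n = 10, seed = 8, duration = 720)
  st <- algorithm_settings("dynamic", 8, 5)
  curve <- power_curve(co, st, n_values = c(4, 10, 30), iters = 40, seed = 4)
  expect_equal(nrow(curve), 3)
  cross <- attr(curve, "crossings")
  expect_equal(nrow(cross), 3)
  for (i in seq_len(nrow(cross))) {
    th <- cross$threshold[i]
    if (!is.na(cross$n_required[i])) {
      expect_gte(curve$power[curve$n == cross$n_required[i]], th)
    } else {
      expect_true(all(curve$power < th, na.rm = TRUE))
    }
  }
  expect_error(power_curve(co, st, n_values = 10), "n_values")
})
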