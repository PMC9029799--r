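# Independent oracles kept deliberately naive; they never call the code paths
# they check.

# closed-form two-parameter least squares
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# full O(T * n) re-scan of the k-of-n trigger rule with refractory period:
# re-checks every window and the silent constraint from scratch
naive_trigger_oracle <- function(flags, window_length, window_threshold,
                                 silent_min) {
  n <- length(flags)
  triggers <- integer(0)
  for (t in seq_len(n)) {
    if (t < window_length) next
    if (sum(flags[(t - window_length + 1):t]) < window_threshold) next
    t0 <- t - 1L  # 0-based
    if (length(triggers) && t0 - triggers[length(triggers)] <= silent_min) next
    triggers <- c(triggers, t0)
  }
  triggers
}

# brute-force transition/trigger pairing over a half-open follow window
naive_match_oracle <- function(transition_minutes, trigger_minutes,
                               follow_window) {
  vapply(transition_minutes, function(t0) {
    hit <- FALSE
    for (tr in trigger_minutes) {
      if (tr > t0 && tr <= t0 + follow_window) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

# convenience: a series with exact linear RMSSD ~ AEE structure
make_linear_series <- function(id = "p", n = 120, intercept = 50, slope = -6,
                               aee = NULL, noise = 0, stress_level = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(aee)) aee <- seq(0.2, 3, length.out = n)
  rmssd <- intercept + slope * aee + noise * stats::rnorm(length(aee))
  participant_series(id, rmssd, aee, stress_level = stress_level)
}

# small cohort wrapper for evaluation tests
small_cohort <- function(effect_drop = 10, n = 12, seed = 1,
                         duration = 720) {
  generate_cohort(generator_params(
    n_participants = n, duration_min = duration,
    effect_drop = effect_drop, seed = seed
  ))
}
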