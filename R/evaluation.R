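#' Random-intercept logistic model of stress direction on trigger presence
#'
#' Fits `direction ~ trigger_present + (1 | participant)` with a logit link
#' and Gaussian random intercepts via [lme4::glmer()] (Laplace
#' approximation), the model that decides whether triggers predict increases
#' rather than decreases of objective stress. The p-value is the Wald test on
#' the trigger coefficient; a likelihood-ratio test is available. With the
#' intercept variance constrained to zero — or with a single grouping level —
#' the model reduces to ordinary logistic regression and is fit with
#' [stats::glm()].
#'
#' Degenerate inputs (constant outcome, constant predictor, or a zero cell in
#' the direction-by-trigger 2x2 table, i.e. complete separation) yield
#' `converged = FALSE` rather than an error, so bootstrap iterations can be
#' marked invalid and continue.
#'
#' @param events Data.frame of event records with columns `participant_id`,
#'   `direction` (1 = stress increase), `trigger_present` (0/1).
#' @param constrain_zero_variance If `TRUE`, fix the random-intercept
#'   variance at zero (plain logistic regression).
#' @param test `"wald"` (default) or `"lrt"` for the trigger p-value.
#' @return An object of class `hrv_model_fit`: list with `beta_trigger`,
#'   `se`, `p_value`, `odds_ratio`, `converged`, `n_events`,
#'   `n_participants`.
#' @export
fit_random_intercept_logistic <- function(events,
                                          constrain_zero_variance = FALSE,
                                          test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(events),
            all(c("participant_id", "direction", "trigger_present")
                %in% names(events)))
  bad <- function() {
    structure(
      list(beta_trigger = NA_real_, se = NA_real_, p_value = NA_real_,
           odds_ratio = NA_real_, converged = FALSE,
           n_events = nrow(events),
           n_participants = length(unique(events$participant_id))),
      class = "hrv_model_fit"
    )
  }
  if (nrow(events) < 2L) return(bad())
  y <- events$direction
  x <- events$trigger_present
  tab <- table(factor(y, levels = 0:1), factor(x, levels = 0:1))
  # constant outcome/predictor or complete separation: no finite estimate
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) || any(tab == 0L)) {
    return(bad())
  }
  pid <- factor(events$participant_id)
  fit <- tryCatch({
    if (constrain_zero_variance || nlevels(pid) < 2L) {
      m <- stats::glm(y ~ x, family = stats::binomial())
      co <- summary(m)$coefficients
      list(beta = co["x", 1], se = co["x", 2],
           dev_full = m$deviance,
           dev_null = stats::glm(y ~ 1,
                                 family = stats::binomial())$deviance)
    } else {
      m <- suppressMessages(suppressWarnings(
        lme4::glmer(y ~ x + (1 | pid), family = stats::binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
      ))
      co <- summary(m)$coefficients
      out <- list(beta = co["x", 1], se = co["x", 2])
      if (test == "lrt") {
        m0 <- suppressMessages(suppressWarnings(
          lme4::glmer(y ~ 1 + (1 | pid), family = stats::binomial(),
                      control = lme4::glmerControl(calc.derivs = FALSE,
                                                   check.conv.singular = "ignore"))
        ))
        out$dev_full <- stats::deviance(m)
        out$dev_null <- stats::deviance(m0)
      }
      out
    }
  }, error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$beta) || !is.finite(fit$se) ||
      abs(fit$beta) > 15) {
    return(bad())
  }
  p <- if (test == "wald") {
    2 * stats::pnorm(-abs(fit$beta / fit$se))
  } else {
    stats::pchisq(max(0, fit$dev_null - fit$dev_full), df = 1,
                  lower.tail = FALSE)
  }
  structure(
    list(beta_trigger = fit$beta, se = fit$se, p_value = p,
         odds_ratio = exp(fit$beta), converged = TRUE,
         n_events = nrow(events), n_participants = nlevels(pid)),
    class = "hrv_model_fit"
  )
}

#' @export
print.hrv_model_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<hrv_model_fit> beta=%.3f (SE %.3f), OR=%.2f, p=%.4f, %d events / %d participants\n",
      x$beta_trigger, x$se, x$odds_ratio, x$p_value, x$n_events,
      x$n_participants
    ))
  } else {
    cat("<hrv_model_fit> not converged (degenerate or separated data)\n")
  }
  invisible(x)
}

# Precompute each participant's event records for one algorithm setting.
# Returns a list of data.frames (possibly zero-row), one per participant.
cohort_events <- function(cohort, settings, follow_window = 20L,
                          min_duration = 20L, models = NULL,
                          screen = TRUE) {
  stopifnot(inherits(cohort, "hrv_cohort"),
            inherits(settings, "algorithm_settings"))
  if (is.null(models)) {
    models <- cohort_calibrations(
      cohort,
      predictor_kind = if (settings$variant == "inverse") "inverse" else "linear",
      screen = screen
    )
  }
  lapply(seq_along(cohort$series), function(i) {
    s <- cohort$series[[i]]
    train <- run_algorithm(s, models[[i]], settings)
    tr <- detect_transitions(s, min_duration = min_duration)
    ev <- match_triggers(tr, train, follow_window = follow_window)
    attr(ev, "n_triggers") <- length(train$trigger_minutes)
    ev
  })
}

#' Fit calibration models for every participant of a cohort
#'
#' @param cohort A [generate_cohort()] result (or any `hrv_cohort`).
#' @param predictor_kind Passed to [fit_calibration()].
#' @param screen If `TRUE`, run [screen_outliers()] first.
#' @return List of [fit_calibration()] results.
#' @export
cohort_calibrations <- function(cohort, predictor_kind = "linear",
                                screen = TRUE) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  lapply(cohort$series, function(s) {
    if (screen) s <- screen_outliers(s)
    fit_calibration(s, predictor_kind = predictor_kind)
  })
}

# One cluster-bootstrap pass over precomputed per-participant event tables.
# Resampled participants entering more than once get fresh grouping labels.
bootstrap_events_once <- function(event_list, n_draw) {
  idx <- sample.int(length(event_list), n_draw, replace = TRUE)
  pieces <- lapply(seq_along(idx), function(j) {
    ev <- event_list[[idx[j]]]
    if (!nrow(ev)) return(NULL)
    data.frame(participant_id = sprintf("b%04d", j),
               direction = ev$direction,
               trigger_present = ev$trigger_present)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(NULL)
  do.call(rbind, pieces)
}

#' Bootstrap evaluation of one algorithm setting
#'
#' The second simulation step for a single setting: trigger trains, stress
#' transitions and event records are computed once per participant (the
#' engine is deterministic), then `iters` cluster-bootstrap iterations each
#' resample `n_draw` participants with replacement, pool their events, and
#' fit the random-intercept logistic model. Power is the fraction of valid
#' iterations with p < 0.05; the effect estimate is the mean percentage
#' change in odds, `(OR - 1) * 100`, with 2.5/97.5 percentile confidence
#' bounds. Iterations with degenerate resamples (constant outcome or
#' predictor, separation, non-convergence) are marked invalid.
#'
#' @param cohort An `hrv_cohort`.
#' @param settings An [algorithm_settings()].
#' @param iters Bootstrap iterations (default 500).
#' @param seed Integer seed; the result is a pure function of inputs + seed.
#' @param n_draw Participants drawn per iteration (default: cohort size).
#' @param follow_window,min_duration Passed to the event-matching step.
#' @param models Optional precomputed calibration models.
#' @param event_list Optional precomputed result of the internal
#'   event-building step, for sweeps that share it across settings.
#' @return An object of class `setting_result`: one-row data.frame with
#'   columns `variant`, `window_length`, `window_threshold`, `silent_min`,
#'   `power`, `mean_pct_odds`, `ci_low`, `ci_high`, `total_triggers`,
#'   `triggered_increases`, `triggered_decreases`, `n_valid_iters`, `iters`,
#'   `unreliable`.
#' @export
bootstrap_setting <- function(cohort, settings, iters = 500L, seed = 1L,
                              n_draw = NULL, follow_window = 20L,
                              min_duration = 20L, models = NULL,
                              event_list = NULL) {
  if (is.null(event_list)) {
    event_list <- cohort_events(cohort, settings,
                                follow_window = follow_window,
                                min_duration = min_duration, models = models)
  }
  if (is.null(n_draw)) n_draw <- length(event_list)
  total_triggers <- sum(vapply(event_list, attr, numeric(1), "n_triggers"))
  set.seed(as.integer(seed))
  p_vals <- rep(NA_real_, iters)
  ors <- rep(NA_real_, iters)
  inc <- rep(NA_real_, iters)
  dec <- rep(NA_real_, iters)
  for (b in seq_len(iters)) {
    ev <- bootstrap_events_once(event_list, n_draw)
    if (is.null(ev)) next
    fit <- fit_random_intercept_logistic(ev)
    if (!fit$converged) next
    p_vals[b] <- fit$p_value
    ors[b] <- fit$odds_ratio
    inc[b] <- sum(ev$direction == 1L & ev$trigger_present == 1L)
    dec[b] <- sum(ev$direction == 0L & ev$trigger_present == 1L)
  }
  valid <- is.finite(p_vals)
  nv <- sum(valid)
  pct <- (ors[valid] - 1) * 100
  res <- data.frame(
    variant = settings$variant,
    window_length = settings$window_length,
    window_threshold = settings$window_threshold,
    silent_min = settings$silent_min,
    power = if (nv) mean(p_vals[valid] < 0.05) else NA_real_,
    mean_pct_odds = if (nv) mean(pct) else NA_real_,
    ci_low = if (nv) unname(stats::quantile(pct, 0.025)) else NA_real_,
    ci_high = if (nv) unname(stats::quantile(pct, 0.975)) else NA_real_,
    total_triggers = total_triggers,
    triggered_increases = if (nv) mean(inc[valid]) else NA_real_,
    triggered_decreases = if (nv) mean(dec[valid]) else NA_real_,
    n_valid_iters = nv,
    iters = iters,
    unreliable = nv < iters / 2
  )
  class(res) <- c("setting_result", class(res))
  res
}

#' Sweep the settings grid with bootstrap evaluation
#'
#' Runs [bootstrap_setting()] for every (window length, window threshold)
#' pair of the grid — 435 settings for the canonical 2..30 range — for one
#' algorithm variant. Decrease flags are computed once per participant and
#' reused across settings; only the k-out-of-n scan and the bootstrap differ
#' per setting.
#'
#' @param cohort An `hrv_cohort`.
#' @param variant `"static"`, `"dynamic"` or `"inverse"`.
#' @param min_len,max_len Grid bounds passed to [enumerate_settings()].
#' @param silent_min,follow_window,min_duration Algorithm and matching
#'   parameters.
#' @param iters Bootstrap iterations per setting.
#' @param seed Master seed; each setting uses a seed derived from it.
#' @return A data.frame with one [bootstrap_setting()] row per setting,
#'   ordered by decreasing power (ties broken by grid order), plus an
#'   attribute `grid` holding the power matrix in long format.
#' @export
sweep_grid <- function(cohort, variant = c("static", "dynamic", "inverse"),
                       min_len = 2L, max_len = 30L, silent_min = 20L,
                       follow_window = 20L, min_duration = 20L,
                       iters = 500L, seed = 1L) {
  variant <- match.arg(variant)
  grid <- enumerate_settings(min_len, max_len)
  models <- cohort_calibrations(
    cohort,
    predictor_kind = if (variant == "inverse") "inverse" else "linear"
  )
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- algorithm_settings(variant, grid$window_length[g],
                             grid$window_threshold[g],
                             silent_min = silent_min)
    rows[[g]] <- bootstrap_setting(
      cohort, st, iters = iters, seed = (as.integer(seed) + 7919L * g) %% .Machine$integer.max,
      follow_window = follow_window, min_duration = min_duration,
      models = models
    )
  }
  out <- do.call(rbind, rows)
  long <- out[, c("window_length", "window_threshold", "power",
                  "mean_pct_odds")]
  out <- out[order(-out$power), ]
  rownames(out) <- NULL
  attr(out, "grid") <- long
  out
}

#' Rejection rate over independent generated cohorts
#'
#' Monte-Carlo calibration of the evaluation pipeline: draws `n_cohorts`
#' independent cohorts from the generator, runs the full step-1/step-2 path
#' on each (calibration, triggers, transitions, one random-intercept
#' logistic fit) and returns the fraction of valid fits with p < 0.05.
#' With `effect_drop = 0` in `params` this is the type-I error of the
#' trigger test; note that it is a different quantity from the
#' cluster-bootstrap "power" of [bootstrap_setting()], which concentrates on
#' the realised association of its single input cohort and is therefore not
#' expected to approach 0.05 under the null.
#'
#' @param params A [generator_params()]; its `seed` is ignored in favour of
#'   seeds derived from `seed`.
#' @param settings An [algorithm_settings()].
#' @param n_cohorts Number of independent cohorts (default 500).
#' @param seed Master seed.
#' @param follow_window,min_duration Passed to the event-matching step.
#' @return A list with `rate` (rejection fraction among valid fits),
#'   `n_valid`, `n_cohorts`.
#' @export
null_rejection_rate <- function(params, settings, n_cohorts = 500L,
                                seed = 1L, follow_window = 20L,
                                min_duration = 20L) {
  stopifnot(inherits(params, "generator_params"),
            inherits(settings, "algorithm_settings"))
  set.seed(as.integer(seed))
  cohort_seeds <- sample.int(.Machine$integer.max, n_cohorts)
  rej <- vapply(seq_len(n_cohorts), function(r) {
    params$seed <- cohort_seeds[r]
    co <- generate_cohort(params)
    ev <- do.call(rbind, cohort_events(co, settings,
                                       follow_window = follow_window,
                                       min_duration = min_duration))
    fit <- fit_random_intercept_logistic(ev)
    if (!fit$converged) return(NA_real_)
    as.numeric(fit$p_value < 0.05)
  }, numeric(1))
  list(rate = mean(rej, na.rm = TRUE), n_valid = sum(!is.na(rej)),
       n_cohorts = n_cohorts)
}

#' Power as a function of cohort size
#'
#' For each candidate sample size n, runs the cluster bootstrap drawing n
#' participants with replacement per iteration and records the resulting
#' power, tracing how large an online study must be for the chosen setting
#' to detect stress increases reliably.
#'
#' @param cohort An `hrv_cohort`.
#' @param settings An [algorithm_settings()].
#' @param n_values Integer vector of sample sizes (at least 2).
#' @param iters Bootstrap iterations per sample size.
#' @param seed Master seed.
#' @param thresholds Power thresholds to report crossings for.
#' @param follow_window,min_duration Passed through.
#' @return A data.frame with columns `n` and `power`, with attribute
#'   `crossings`: for each threshold, the smallest n whose power reaches it
#'   (NA if never reached).
#' @export
power_curve <- function(cohort, settings, n_values, iters = 500L, seed = 1L,
                        thresholds = c(0.70, 0.80, 0.90),
                        follow_window = 20L, min_duration = 20L) {
  stopifnot(length(n_values) >= 2L)
  event_list <- cohort_events(cohort, settings,
                              follow_window = follow_window,
                              min_duration = min_duration)
  pw <- vapply(seq_along(n_values), function(i) {
    bootstrap_setting(
      cohort, settings, iters = iters,
      seed = (as.integer(seed) + 104729L * i) %% .Machine$integer.max,
      n_draw = n_values[i], event_list = event_list
    )$power
  }, numeric(1))
  out <- data.frame(n = as.integer(n_values), power = pw)
  attr(out, "crossings") <- data.frame(
    threshold = thresholds,
    n_required = vapply(thresholds, function(th) {
      ok <- out$n[!is.na(out$power) & out$power >= th]
      if (length(ok)) min(ok) else NA_integer_
    }, integer(1))
  )
  out
}
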