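#' Parameters for the synthetic firefighter-day generator
#'
#' Defines the population from which synthetic minute-level days are drawn.
#' Defaults reproduce the calibration heterogeneity of a 38-person
#' firefighter cohort: person intercepts ~ N(51.05, 24.04) ms (truncated
#' low), slopes ~ N(-5.96, 4.46) ms per (kcal/min) (truncated negative),
#' stress-level occupancies 81.4% / 11.2% / 7.4% with episodes of at least
#' `episode_min` minutes, and AR(1) RMSSD noise. AEE is carried in kcal per
#' minute (~0.7 at rest, bursts during operations and occasional exercise
#' bouts), so daily totals land near 1000 kcal.
#'
#' @param n_participants Cohort size (default 38).
#' @param duration_min Minutes per recording (default 1440, one day).
#' @param intercept_mean,intercept_sd Population of calibration intercepts
#'   (ms); draws truncated at 18 ms.
#' @param slope_mean,slope_sd Population of calibration slopes in ms per
#'   (kcal/min); draws truncated at -0.4 (always negative).
#' @param resid_sd Marginal SD of the AR(1) RMSSD residual (ms).
#' @param ar1_phi Lag-1 autocorrelation of the RMSSD residual.
#' @param aee_base Resting AEE level (kcal/min).
#' @param aee_burst AEE elevation during routine operations (kcal/min);
#'   emergency operations add 1.6 times this.
#' @param aee_noise_sd Minute-level AEE noise SD (kcal/min).
#' @param p_levels Target occupancies of stress levels 0/1/2 (must sum to 1).
#' @param episode_min Minimum episode duration (minutes, >= 20).
#' @param mean_op_duration Mean operation-episode duration (minutes).
#' @param p_op_chain Probability that an operation transitions into the other
#'   operation level instead of returning to routine work.
#' @param effect_drop Ground-truth RMSSD suppression (ms) applied after each
#'   upward stress transition; 0 gives a null cohort.
#' @param effect_duration Duration of the suppression (minutes).
#' @param invalid_frac Fraction of minutes marked artifact-invalid.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_participants = 38L, duration_min = 1440L,
                             intercept_mean = 51.05, intercept_sd = 24.04,
                             slope_mean = -5.96, slope_sd = 4.46,
                             resid_sd = 11, ar1_phi = 0.6,
                             aee_base = 0.4, aee_burst = 1.2,
                             aee_noise_sd = 0.25,
                             p_levels = c(0.814, 0.112, 0.074),
                             episode_min = 20L, mean_op_duration = 51,
                             p_op_chain = 0.25,
                             effect_drop = 10, effect_duration = 15L,
                             invalid_frac = 0.01, seed = 1L) {
  stopifnot(
    n_participants >= 1L,
    intercept_sd >= 0, slope_sd >= 0, resid_sd >= 0,
    ar1_phi >= 0, ar1_phi < 1,
    aee_base >= 0, aee_burst >= 0, aee_noise_sd >= 0,
    length(p_levels) == 3L, all(p_levels >= 0),
    abs(sum(p_levels) - 1) < 1e-8,
    episode_min >= 20L, mean_op_duration >= episode_min,
    p_op_chain >= 0, p_op_chain < 1,
    effect_drop >= 0, effect_duration >= 0,
    invalid_frac >= 0, invalid_frac < 1
  )
  if (duration_min < 2L * episode_min) {
    stop("duration_min too short for the minimum episode duration",
         call. = FALSE)
  }
  structure(
    as.list(environment()),
    class = "generator_params"
  )
}

# shifted-geometric episode duration with a floor and a given mean
r_episode <- function(n, floor_min, mean_min) {
  extra <- mean_min - floor_min
  if (extra <= 0) return(rep(as.integer(floor_min), n))
  as.integer(floor_min) + stats::rgeom(n, 1 / (extra + 1))
}

# semi-Markov stress schedule honoring the occupancy targets approximately:
# routine episodes alternate with chains of operation episodes
make_schedule <- function(params) {
  p <- params$p_levels
  n <- params$duration_min
  if (p[2] + p[3] <= 0) return(rep(0L, n))
  # mean routine duration solving occ0 = d0 / (d0 + E[ops per chain] * d_op)
  ops_per_chain <- 1 / (1 - params$p_op_chain)
  d_op <- params$mean_op_duration
  occ0 <- p[1]
  d0 <- max(params$episode_min,
            occ0 / max(1 - occ0, 1e-8) * ops_per_chain * d_op)
  lev <- integer(0)
  state <- 0L
  while (length(lev) < n) {
    dur <- if (state == 0L) {
      r_episode(1, params$episode_min, d0)
    } else {
      r_episode(1, params$episode_min, d_op)
    }
    lev <- c(lev, rep(state, dur))
    state <- if (state == 0L) {
      if (stats::runif(1) < p[2] / (p[2] + p[3])) 1L else 2L
    } else if (stats::runif(1) < params$p_op_chain) {
      3L - state  # hop to the other operation level
    } else 0L
  }
  lev[seq_len(n)]
}

#' Generate one synthetic participant day with known ground truth
#'
#' Draws person-level calibration parameters, builds a semi-Markov stress
#' schedule with episodes of at least `episode_min` minutes, lays down AEE
#' (rest baseline, operation bursts, occasional exercise bouts during routine
#' work), and produces RMSSD as `intercept + slope * aee` plus AR(1) noise,
#' suppressed by `effect_drop` ms for `effect_duration` minutes after every
#' upward stress transition. About `invalid_frac` of minutes are marked
#' artifact-invalid.
#'
#' @param params A [generator_params()].
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Identifier (default derived from the seed).
#' @return A list with elements `series` (a [participant_series()]) and
#'   `truth` (one-row data.frame of the generating draws plus the upward
#'   transition minutes as a list column).
#' @export
generate_participant <- function(params, participant_seed,
                                 participant_id = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(participant_id)) {
    participant_id <- sprintf("sim%08x", as.integer(participant_seed))
  }
  set.seed(as.integer(participant_seed))
  n <- params$duration_min

  intercept <- max(18, stats::rnorm(1, params$intercept_mean,
                                    params$intercept_sd))
  slope <- min(-0.4, stats::rnorm(1, params$slope_mean, params$slope_sd))

  lev <- make_schedule(params)

  # AEE: rest baseline, operation bursts, plus exercise bouts at rest
  aee_mean <- params$aee_base +
    ifelse(lev == 1L, params$aee_burst,
           ifelse(lev == 2L, 1.6 * params$aee_burst, 0))
  n_bouts <- stats::rpois(1, 2)
  if (n_bouts > 0 && any(lev == 0L)) {
    for (b in seq_len(n_bouts)) {
      start <- sample.int(n, 1)
      len <- 10L + stats::rgeom(1, 1 / 16)
      idx <- start:min(n, start + len - 1L)
      idx <- idx[lev[idx] == 0L]
      aee_mean[idx] <- aee_mean[idx] + stats::runif(1, 1, 3)
    }
  }
  aee <- pmax(0, aee_mean + stats::rnorm(n, 0, params$aee_noise_sd))

  # AR(1) residual with the requested marginal SD
  innov_sd <- params$resid_sd * sqrt(1 - params$ar1_phi^2)
  noise <- if (params$resid_sd > 0) {
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), params$ar1_phi,
                             method = "recursive",
                             init = stats::rnorm(1, 0, params$resid_sd)))
  } else {
    numeric(n)
  }

  # ground-truth suppression after every upward level change
  effect <- numeric(n)
  up <- which(diff(lev) > 0) + 1L  # 1-based first minute of the higher level
  if (params$effect_drop > 0 && params$effect_duration > 0) {
    for (u in up) {
      idx <- u:min(n, u + params$effect_duration - 1L)
      effect[idx] <- params$effect_drop
    }
  }
  rmssd <- intercept + slope * aee + noise - effect

  valid <- rep(TRUE, n)
  if (params$invalid_frac > 0) {
    valid[stats::runif(n) < params$invalid_frac] <- FALSE
  }

  series <- participant_series(participant_id, rmssd, aee, valid = valid,
                               stress_level = lev)
  truth <- data.frame(
    participant_id = participant_id,
    seed = as.integer(participant_seed),
    intercept = intercept,
    slope = slope,
    effect_drop = params$effect_drop,
    effect_duration = params$effect_duration
  )
  truth$increase_minutes <- I(list(up - 1L))  # 0-based
  list(series = series, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws `n_participants` independent days; per-participant seeds are derived
#' deterministically from the master seed, so identical parameters reproduce
#' identical cohorts.
#'
#' @param params A [generator_params()].
#' @return An object of class `hrv_cohort`: list with `series` (list of
#'   [participant_series()]), `truth` (row-bound ground-truth table) and
#'   `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(as.integer(params$seed))
  seeds <- sample.int(.Machine$integer.max, params$n_participants)
  out <- lapply(seq_len(params$n_participants), function(i) {
    generate_participant(params, seeds[i],
                         participant_id = sprintf("sim%03d", i))
  })
  structure(
    list(
      series = lapply(out, `[[`, "series"),
      truth = do.call(rbind, lapply(out, `[[`, "truth")),
      params = params
    ),
    class = "hrv_cohort"
  )
}

#' @export
print.hrv_cohort <- function(x, ...) {
  cat(sprintf(
    "<hrv_cohort> %d participants x %d min (effect_drop=%g ms, seed=%d)\n",
    length(x$series), x$params$duration_min, x$params$effect_drop,
    x$params$seed
  ))
  invisible(x)
}
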