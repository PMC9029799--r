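#' Algorithm settings for AddHRVr trigger detection
#'
#' Bundles the tunable parameters of the k-out-of-n trigger rule. A trigger
#' fires at the minute completing a trailing window of `window_length` minutes
#' that contains at least `window_threshold` meaningful-decrease flags,
#' provided strictly more than `silent_min` minutes have elapsed since the
#' previous trigger. A meaningful decrease is a valid minute whose observed
#' RMSSD lies below the metabolically expected RMSSD by more than
#' `decrease_mult` times the SD of the calibration RMSSD.
#'
#' @param variant `"static"` (fixed regression intercept), `"dynamic"`
#'   (intercept replaced by the mean of a trailing HRV buffer, see
#'   [run_dynamic_state()]) or `"inverse"` (calibration on reciprocal AEE).
#' @param window_length Window length n in minutes, 2..30.
#' @param window_threshold Required decrease count k, 1..n-1.
#' @param silent_min Refractory period after a trigger (default 20 min).
#' @param decrease_mult Threshold multiplier of the calibration RMSSD SD
#'   (default 0.5).
#' @param hrv_buffer_min Length of the HRV buffer (dynamic variant, default 60).
#' @param aee_buffer_min Length of the AEE buffer (dynamic variant, default 40).
#' @return An object of class `algorithm_settings`.
#' @export
algorithm_settings <- function(variant = c("static", "dynamic", "inverse"),
                               window_length, window_threshold,
                               silent_min = 20L, decrease_mult = 0.5,
                               hrv_buffer_min = 60L, aee_buffer_min = 40L) {
  variant <- match.arg(variant)
  window_length <- as.integer(window_length)
  window_threshold <- as.integer(window_threshold)
  if (window_length < 2L || window_length > 30L) {
    stop("window_length must be in 2..30", call. = FALSE)
  }
  if (window_threshold < 1L || window_threshold > window_length - 1L) {
    stop("window_threshold must be in 1..window_length-1", call. = FALSE)
  }
  if (silent_min < 0L) stop("silent_min must be >= 0", call. = FALSE)
  if (decrease_mult <= 0) stop("decrease_mult must be > 0", call. = FALSE)
  structure(
    list(
      variant = variant, window_length = window_length,
      window_threshold = window_threshold, silent_min = as.integer(silent_min),
      decrease_mult = decrease_mult,
      hrv_buffer_min = as.integer(hrv_buffer_min),
      aee_buffer_min = as.integer(aee_buffer_min)
    ),
    class = "algorithm_settings"
  )
}

#' @export
print.algorithm_settings <- function(x, ...) {
  cat(sprintf(
    "<algorithm_settings> %s %d-out-of-%d, silent %d min, threshold %.2f x SD\n",
    x$variant, x$window_threshold, x$window_length, x$silent_min,
    x$decrease_mult
  ))
  invisible(x)
}

#' Expected RMSSD at a given energy expenditure
#'
#' The metabolically expected RMSSD from the calibration regression:
#' `intercept + slope * predictor(aee)`, where the predictor is AEE itself for
#' the linear kind and `1/(aee + epsilon)` for the inverse kind. The dynamic
#' algorithm substitutes the trailing-buffer mean for the intercept while
#' retaining the slope term, so it degenerates exactly to the static
#' prediction when the buffer mean equals the static intercept.
#'
#' @param model A [fit_calibration()] result.
#' @param aee Numeric AEE value(s) in kcal/min.
#' @param dynamic_intercept Optional replacement intercept(s) in ms, supplied
#'   by the dynamic variant.
#' @return Expected RMSSD in ms (vectorised over `aee`).
#' @export
expected_rmssd <- function(model, aee, dynamic_intercept = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  pred <- if (model$predictor_kind == "inverse") {
    1 / (aee + model$epsilon)
  } else {
    aee
  }
  icpt <- if (is.null(dynamic_intercept)) model$intercept else dynamic_intercept
  icpt + model$slope * pred
}

#' Per-minute dynamic intercept from trailing HRV/AEE buffers
#'
#' Maintains an HRV ring buffer (default 60 min, initialised at the static
#' intercept) and an AEE ring buffer (default 40 min, initialised at the mean
#' calibration AEE). At each minute the dynamic intercept is the current HRV
#' buffer mean, computed before the minute's own values are pushed, so a
#' minute never dilutes its own detection threshold. The HRV buffer then
#' absorbs the observed RMSSD only while the AEE buffer mean is below the
#' calibration mean — i.e. while HRV is not confounded by metabolic load —
#' and the static intercept otherwise; the AEE buffer always absorbs the
#' minute's AEE. Invalid minutes push the neutral values (static intercept,
#' mean calibration AEE).
#'
#' @param series A [participant_series()].
#' @param model A linear-kind [fit_calibration()] result.
#' @param settings An [algorithm_settings()] (buffer lengths are taken from
#'   it).
#' @return Numeric vector of dynamic intercepts (ms), one per minute.
#' @export
run_dynamic_state <- function(series, model, settings) {
  stopifnot(inherits(series, "participant_series"),
            inherits(model, "calibration_model"))
  if (model$predictor_kind != "linear") {
    stop("the dynamic variant requires a linear-kind calibration model",
         call. = FALSE)
  }
  d <- series$data
  n <- nrow(d)
  nh <- settings$hrv_buffer_min
  na_ <- settings$aee_buffer_min
  hrv_buf <- rep(model$intercept, nh)
  aee_buf <- rep(model$mean_aee_cal, na_)
  hrv_sum <- sum(hrv_buf)
  aee_sum <- sum(aee_buf)
  hi <- ai <- 1L
  out <- numeric(n)
  for (t in seq_len(n)) {
    out[t] <- hrv_sum / nh
    if (d$valid[t]) {
      push_hrv <- if (aee_sum / na_ < model$mean_aee_cal) d$rmssd[t] else model$intercept
      push_aee <- d$aee[t]
    } else {
      push_hrv <- model$intercept
      push_aee <- model$mean_aee_cal
    }
    hrv_sum <- hrv_sum - hrv_buf[hi] + push_hrv
    hrv_buf[hi] <- push_hrv
    hi <- if (hi == nh) 1L else hi + 1L
    aee_sum <- aee_sum - aee_buf[ai] + push_aee
    aee_buf[ai] <- push_aee
    ai <- if (ai == na_) 1L else ai + 1L
  }
  out
}

#' Flag meaningful RMSSD decreases
#'
#' Classifies each valid minute as a meaningful decrease when the observed
#' RMSSD falls below the expected RMSSD minus `decrease_mult` times the
#' calibration RMSSD SD. Invalid minutes are never flagged. The per-minute
#' threshold line (expected minus margin) is returned for audit and plotting.
#'
#' @param series A [participant_series()].
#' @param model A [fit_calibration()] result for the same participant.
#' @param settings An [algorithm_settings()].
#' @param dynamic_intercept Optional per-minute intercept trace from
#'   [run_dynamic_state()]; computed internally when the variant is dynamic.
#' @return A list with logical `decrease_flags` and numeric `threshold_trace`
#'   (ms), one element per minute.
#' @export
flag_decreases <- function(series, model, settings, dynamic_intercept = NULL) {
  stopifnot(inherits(series, "participant_series"),
            inherits(model, "calibration_model"))
  if (!identical(series$participant_id, model$participant_id)) {
    stop("series and calibration model belong to different participants",
         call. = FALSE)
  }
  if (settings$variant == "dynamic" && is.null(dynamic_intercept)) {
    dynamic_intercept <- run_dynamic_state(series, model, settings)
  }
  d <- series$data
  expected <- expected_rmssd(model, d$aee, dynamic_intercept)
  threshold <- expected - settings$decrease_mult * model$sd_rmssd_cal
  flags <- d$valid & !is.na(d$rmssd) & d$rmssd < threshold
  flags[is.na(flags)] <- FALSE
  list(decrease_flags = flags, threshold_trace = threshold)
}

#' Run an AddHRVr trigger algorithm over a recording
#'
#' Streaming, strictly causal simulation of the k-out-of-n trigger rule:
#' minute by minute, decrease flags are computed (with dynamic intercepts when
#' the variant is dynamic), and a trigger is stamped at minute `t` when the
#' trailing window `t - window_length + 1 .. t` holds at least
#' `window_threshold` flags and more than `silent_min` minutes have passed
#' since the previous trigger. No trigger can fire before the first complete
#' window; invalid minutes count as non-decreases but stay inside windows.
#'
#' @param series A [participant_series()].
#' @param model A [fit_calibration()] result; its kind must match the variant
#'   (linear for static/dynamic, inverse for inverse).
#' @param settings An [algorithm_settings()].
#' @return An object of class `trigger_train`: list with `participant_id`,
#'   `settings`, `decrease_flags`, `threshold_trace`, `trigger_minutes`
#'   (0-based minute indices) and `dynamic_intercept` (dynamic variant only).
#' @export
run_algorithm <- function(series, model, settings) {
  stopifnot(inherits(settings, "algorithm_settings"))
  needed <- if (settings$variant == "inverse") "inverse" else "linear"
  if (model$predictor_kind != needed) {
    stop(sprintf("variant '%s' requires a %s-kind calibration model",
                 settings$variant, needed), call. = FALSE)
  }
  dyn <- if (settings$variant == "dynamic") {
    run_dynamic_state(series, model, settings)
  }
  fl <- flag_decreases(series, model, settings, dynamic_intercept = dyn)
  trig <- scan_triggers(fl$decrease_flags, settings$window_length,
                        settings$window_threshold, settings$silent_min)
  structure(
    list(
      participant_id = series$participant_id,
      settings = settings,
      decrease_flags = fl$decrease_flags,
      threshold_trace = fl$threshold_trace,
      trigger_minutes = trig,
      dynamic_intercept = dyn
    ),
    class = "trigger_train"
  )
}

# k-of-n scan with refractory period over a logical flag vector;
# returns 0-based trigger minutes. Shared by run_algorithm and the grid sweep.
scan_triggers <- function(flags, window_length, window_threshold, silent_min) {
  n <- length(flags)
  if (n < window_length) return(integer(0))
  cs <- cumsum(as.integer(flags))
  # window count at 1-based index t (t >= window_length)
  idx <- window_length:n
  counts <- cs[idx] - c(0, cs)[idx - window_length + 1L]
  cand <- idx[counts >= window_threshold] - 1L  # 0-based
  if (!length(cand)) return(integer(0))
  out <- integer(0)
  last <- -Inf
  for (t in cand) {
    if (t - last > silent_min) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' @export
print.trigger_train <- function(x, ...) {
  cat(sprintf(
    "<trigger_train> id=%s %s %d-out-of-%d: %d decrease minutes, %d triggers\n",
    x$participant_id, x$settings$variant, x$settings$window_threshold,
    x$settings$window_length, sum(x$decrease_flags), length(x$trigger_minutes)
  ))
  invisible(x)
}

#' Export a trigger train to a per-minute table
#'
#' @param train A [run_algorithm()] result.
#' @param path Optional CSV output path.
#' @return A data.frame with columns `minute`, `decrease_flag`,
#'   `threshold_trace`, `trigger`.
#' @export
trigger_train_table <- function(train, path = NULL) {
  stopifnot(inherits(train, "trigger_train"))
  n <- length(train$decrease_flags)
  tab <- data.frame(
    minute = 0:(n - 1L),
    decrease_flag = as.integer(train$decrease_flags),
    threshold_trace = train$threshold_trace,
    trigger = as.integer((0:(n - 1L)) %in% train$trigger_minutes)
  )
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Enumerate the window-length / window-threshold settings grid
#'
#' All (window_length, window_threshold) pairs with threshold from 1 to
#' length - 1, lexicographically ordered; lengths 2..30 give the canonical
#' 435-setting grid.
#'
#' @param min_len Smallest window length (default 2).
#' @param max_len Largest window length (default 30).
#' @return A data.frame with columns `window_length`, `window_threshold`.
#' @export
enumerate_settings <- function(min_len = 2L, max_len = 30L) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  if (max_len < min_len) stop("max_len must be >= min_len", call. = FALSE)
  lens <- rep(min_len:max_len, times = (min_len:max_len) - 1L)
  thrs <- unlist(lapply(min_len:max_len, function(L) seq_len(L - 1L)))
  data.frame(window_length = lens, window_threshold = thrs)
}
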