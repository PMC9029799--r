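#' Detect objective stress transitions under a minimum-episode rule
#'
#' Run-length encodes the minute-level objective stress codes
#' (0 = routine station work, 1 = routine operation, 2 = emergency operation)
#' and emits a transition at every level boundary whose preceding and
#' following episodes each last at least `min_duration` minutes. Transitions
#' flanked by a shorter episode are dropped entirely, which guarantees the
#' follow windows of consecutive transitions cannot nest; episodes touching
#' the recording boundaries still count as flanking context through their
#' observed length. Direction is 1 for an increase of objective stress and 0
#' for a decrease.
#'
#' @param series A [participant_series()] with a stress code on every minute.
#' @param min_duration Minimum duration of both flanking episodes (default 20
#'   min).
#' @return A data.frame with one row per transition: `participant_id`,
#'   `t_min` (first minute of the new level), `from_level`, `to_level`,
#'   `direction`.
#' @export
detect_transitions <- function(series, min_duration = 20L) {
  stopifnot(inherits(series, "participant_series"))
  lev <- series$data$stress_level
  if (anyNA(lev)) {
    stop("missing stress level at minute ",
         series$data$minute[which(is.na(lev))[1]], call. = FALSE)
  }
  r <- rle(as.integer(lev))
  k <- length(r$lengths)
  empty <- data.frame(
    participant_id = character(0), t_min = integer(0),
    from_level = integer(0), to_level = integer(0), direction = integer(0)
  )
  if (k < 2L) return(empty)
  starts <- cumsum(c(0L, r$lengths[-k]))  # 0-based first minute of each run
  keep <- which(r$lengths[-k] >= min_duration & r$lengths[-1] >= min_duration)
  if (!length(keep)) return(empty)
  data.frame(
    participant_id = series$participant_id,
    t_min = starts[keep + 1L],
    from_level = r$values[keep],
    to_level = r$values[keep + 1L],
    direction = as.integer(r$values[keep + 1L] > r$values[keep])
  )
}

#' Match stress transitions with trigger presence in a follow window
#'
#' For each transition, determines whether at least one trigger fired in the
#' half-open follow window `(t_min, t_min + follow_window]`: a trigger at the
#' transition minute itself belongs to the preceding situation, since the
#' trigger must follow the change. Aggregate counts of triggered increases
#' and decreases are attached for reporting.
#'
#' @param transitions A [detect_transitions()] result.
#' @param train A [run_algorithm()] result for the same participant.
#' @param follow_window Follow-window length in minutes (default 20; 40 for
#'   the longer-effects variant).
#' @return A data.frame of event records — columns `participant_id`, `t_min`,
#'   `from_level`, `to_level`, `direction`, `trigger_present` — with
#'   attributes `triggered_increases` and `triggered_decreases`.
#' @export
match_triggers <- function(transitions, train, follow_window = 20L) {
  stopifnot(inherits(train, "trigger_train"), is.data.frame(transitions))
  if (nrow(transitions) &&
      !all(transitions$participant_id == train$participant_id)) {
    stop("transitions and trigger train belong to different participants",
         call. = FALSE)
  }
  tm <- train$trigger_minutes
  present <- vapply(transitions$t_min, function(t0) {
    any(tm > t0 & tm <= t0 + follow_window)
  }, logical(1))
  out <- transitions
  out$trigger_present <- as.integer(present)
  attr(out, "triggered_increases") <- sum(present & transitions$direction == 1L)
  attr(out, "triggered_decreases") <- sum(present & transitions$direction == 0L)
  out
}
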