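#' Construct a minute-level participant series
#'
#' The canonical container consumed by every other function in the package:
#' one row per minute of recording on a contiguous 0-based minute grid, with
#' RMSSD (ms), activity energy expenditure (AEE, kcal per minute), an artifact
#' validity flag and an optional ordinal objective-stress code
#' (0 = routine station work, 1 = routine operation, 2 = emergency operation).
#'
#' Minutes at which the device produced no usable value are represented as
#' `valid = FALSE` rows, never omitted, so that window arithmetic downstream is
#' unambiguous. Non-positive RMSSD and negative AEE are invalidated on
#' construction: the device's own artifact scan is not reproducible here, so
#' the package trusts an incoming validity flag and additionally enforces the
#' physiological range.
#'
#' @param participant_id Opaque participant identifier (length-1 character).
#' @param rmssd Numeric vector of minute RMSSD values in ms (`NA` allowed).
#' @param aee Numeric vector of minute AEE values in kcal (`NA` allowed).
#' @param valid Logical artifact flags; defaults to complete cases of
#'   `rmssd`/`aee`.
#' @param stress_level Optional integer vector of stress codes in `{0, 1, 2}`.
#'
#' @return An object of class `participant_series`: a list with elements
#'   `participant_id`, `data` (a data.frame with columns `minute`, `rmssd`,
#'   `aee`, `valid`, `stress_level`) and `duration_min`.
#' @export
#' @examples
#' s <- participant_series("p1", rmssd = c(50, 48, 52), aee = c(1, 2, 1.5))
#' s$duration_min
participant_series <- function(participant_id, rmssd, aee, valid = NULL,
                               stress_level = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  n <- length(rmssd)
  if (length(aee) != n) {
    stop("rmssd and aee must have the same length", call. = FALSE)
  }
  rmssd <- as.numeric(rmssd)
  aee <- as.numeric(aee)
  if (is.null(valid)) {
    valid <- !is.na(rmssd) & !is.na(aee)
  }
  valid <- as.logical(valid) & !is.na(rmssd) & !is.na(aee)
  valid[is.na(valid)] <- FALSE
  # enforce physiological range: RMSSD must be positive, AEE non-negative
  valid <- valid & is.finite(rmssd) & is.finite(aee) & rmssd > 0 & aee >= 0
  if (!is.null(stress_level)) {
    stress_level <- as.integer(stress_level)
    if (length(stress_level) != n) {
      stop("stress_level must have one value per minute", call. = FALSE)
    }
  } else {
    stress_level <- rep(NA_integer_, n)
  }
  out <- structure(
    list(
      participant_id = participant_id,
      data = data.frame(
        minute = if (n) 0:(n - 1L) else integer(0),
        rmssd = rmssd, aee = aee, valid = valid,
        stress_level = stress_level
      ),
      duration_min = n
    ),
    class = "participant_series"
  )
  out
}

#' @export
print.participant_series <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<participant_series> id=%s  %d min  (%d valid, %.1f%%)\n",
    x$participant_id, x$duration_min, sum(d$valid),
    if (x$duration_min) 100 * mean(d$valid) else 0
  ))
  if (any(!is.na(d$stress_level))) {
    occ <- table(factor(d$stress_level, levels = 0:2))
    cat(sprintf(
      "  stress occupancy: 0=%.1f%% 1=%.1f%% 2=%.1f%%\n",
      100 * occ[1] / x$duration_min, 100 * occ[2] / x$duration_min,
      100 * occ[3] / x$duration_min
    ))
  }
  invisible(x)
}

# default column dialect for CSV import/export
default_dialect <- function() {
  c(
    minute = "minute", rmssd = "rmssd_ms", aee = "aee_kcal",
    valid = "valid", stress_level = "stress_level"
  )
}

#' Read a minute-level series from CSV
#'
#' Reads a comma-separated file with a header row into a
#' [participant_series()]. The default dialect expects columns
#' `minute,rmssd_ms,aee_kcal,valid,stress_level`; other device exports are
#' accommodated by supplying a `dialect` mapping. Timestamps are normalised to
#' a contiguous 0-based minute grid: missing minutes become `valid = FALSE`
#' rows, and rows with non-numeric or out-of-range physiological values are
#' invalidated rather than dropped.
#'
#' @param path Path to a CSV file.
#' @param participant_id Identifier for the series; defaults to the file name
#'   without extension.
#' @param dialect Named character vector mapping the canonical names
#'   `minute`, `rmssd`, `aee`, `valid`, `stress_level` to the file's column
#'   names. `valid` and `stress_level` entries may name absent columns.
#' @return A [participant_series()].
#' @export
read_minute_series <- function(path, participant_id = NULL,
                               dialect = default_dialect()) {
  if (!file.exists(path)) {
    stop("cannot read minute series: no such file: ", path, call. = FALSE)
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  dialect <- as.list(dialect)
  need <- unlist(dialect[c("minute", "rmssd", "aee")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("minute series ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(raw)) {
    return(participant_series(participant_id, numeric(0), numeric(0)))
  }
  minute <- suppressWarnings(as.integer(raw[[dialect[["minute"]]]]))
  if (anyNA(minute)) {
    stop("non-integer minute index in ", path, call. = FALSE)
  }
  dup <- minute[duplicated(minute)]
  if (length(dup)) {
    stop("duplicated minute index ", dup[1], " in ", path, call. = FALSE)
  }
  minute <- minute - min(minute)
  n <- max(minute) + 1L
  num_col <- function(key) {
    out <- rep(NA_real_, n)
    col <- dialect[[key]] %||% NA_character_
    if (!is.null(col) && col %in% names(raw)) {
      out[minute + 1L] <- suppressWarnings(as.numeric(raw[[col]]))
    }
    out
  }
  rmssd <- num_col("rmssd")
  aee <- num_col("aee")
  valid <- rep(FALSE, n)
  vcol <- dialect[["valid"]] %||% NA_character_
  if (!is.null(vcol) && vcol %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[vcol]])) != 0
    v[is.na(v)] <- FALSE
    valid[minute + 1L] <- v
  } else {
    valid[minute + 1L] <- TRUE
  }
  stress <- rep(NA_real_, n)
  scol <- dialect[["stress_level"]] %||% NA_character_
  if (!is.null(scol) && scol %in% names(raw) &&
      any(nzchar(raw[[scol]]))) {
    stress[minute + 1L] <- suppressWarnings(as.numeric(raw[[scol]]))
  }
  participant_series(participant_id, rmssd, aee, valid = valid,
                     stress_level = stress)
}

#' Write a minute-level series to CSV
#'
#' Inverse of [read_minute_series()] under the default dialect: the written
#' file re-reads to a field-for-field identical series. Missing values are
#' written as empty fields and booleans as 0/1.
#'
#' @param series A [participant_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minute_series <- function(series, path) {
  stopifnot(inherits(series, "participant_series"))
  d <- series$data
  out <- data.frame(
    minute = d$minute,
    rmssd_ms = d$rmssd,
    aee_kcal = d$aee,
    valid = as.integer(d$valid),
    stress_level = d$stress_level
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a participant series
#'
#' Checks every container invariant — contiguous 0-based minute grid, positive
#' finite RMSSD and non-negative finite AEE on valid minutes, stress codes in
#' `{0, 1, 2}`, duration bookkeeping — and reports violations instead of
#' raising, so that batch imports can be triaged.
#'
#' @param series A [participant_series()].
#' @return A data.frame with one row per violation, columns `minute` and
#'   `rule`; zero rows iff the series is compliant.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "participant_series"))
  d <- series$data
  bad <- list()
  note <- function(minute, rule) {
    bad[[length(bad) + 1L]] <<- data.frame(minute = minute, rule = rule)
  }
  n <- nrow(d)
  if (series$duration_min != n) {
    note(NA_integer_, "duration_min does not equal the number of records")
  }
  if (n && !identical(as.integer(d$minute), 0:(n - 1L))) {
    brk <- which(d$minute != 0:(n - 1L))[1]
    note(d$minute[brk], "minute grid not contiguous 0-based")
  }
  v <- d$valid
  i <- which(v & (!is.finite(d$rmssd) | d$rmssd <= 0))
  for (m in d$minute[i]) note(m, "valid minute with non-positive or missing rmssd")
  i <- which(v & (!is.finite(d$aee) | d$aee < 0))
  for (m in d$minute[i]) note(m, "valid minute with negative or missing aee")
  i <- which(!is.na(d$stress_level) & !(d$stress_level %in% 0:2))
  for (m in d$minute[i]) note(m, "stress_level outside {0,1,2}")
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(minute = integer(0), rule = character(0))
  }
}

# valid-minute views used throughout the package
valid_rows <- function(series) {
  d <- series$data
  d[d$valid, , drop = FALSE]
}
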