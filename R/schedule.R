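#' Construct a radiotherapy schedule
#'
#' A schedule is an ordered sequence of irradiation events, each a
#' (time in days, dose in Gy) pair. Times are measured from the course start
#' (day 0); only relative times matter to the model. Sub-day timing is
#' expressed in decimal days (6 h = 0.25 d).
#'
#' Events are sorted by time on construction. Events whose times coincide
#' (within 1e-9 d) are merged into a single event with the summed dose: the
#' LQ model is nonlinear in dose, so two truly simultaneous fractions act as
#' one; a zero-width integration window would otherwise contribute nothing.
#'
#' @param time_days Numeric vector of event times, days, all >= 0.
#' @param dose_gy Numeric vector of doses, Gy, all > 0; recycled to the
#'   length of `time_days` if scalar.
#' @return An object of class `rt_schedule`: a data frame with columns
#'   `time_days` and `dose_gy`, one row per event.
#' @examples
#' schedule(c(0, 1, 2), 8)           # 3 x 8 Gy daily
#' schedule(c(0, 0.25), c(2, 2))     # bifractionation, 6 h apart
#' @seealso [schedule_uniform()], [schedule_weekday()], [parse_schedule()]
#' @export
schedule <- function(time_days, dose_gy) {
  if (length(dose_gy) == 1L) dose_gy <- rep(dose_gy, length(time_days))
  if (length(time_days) != length(dose_gy))
    stop("`time_days` and `dose_gy` must have the same length", call. = FALSE)
  if (length(time_days) < 1L)
    stop("a schedule needs at least one irradiation event", call. = FALSE)
  if (!is.numeric(time_days) || any(!is.finite(time_days)) || any(time_days < 0))
    stop("event times must be finite non-negative numbers of days", call. = FALSE)
  if (!is.numeric(dose_gy) || any(!is.finite(dose_gy)) || any(dose_gy <= 0))
    stop("doses must be finite positive numbers of Gy", call. = FALSE)
  ord <- order(time_days, method = "radix")
  t <- as.numeric(time_days)[ord]
  d <- as.numeric(dose_gy)[ord]
  # merge coincident events (summed dose)
  grp <- cumsum(c(TRUE, diff(t) > 1e-9))
  t <- tapply(t, grp, `[`, 1L)
  d <- tapply(d, grp, sum)
  out <- data.frame(time_days = as.numeric(t), dose_gy = as.numeric(d))
  class(out) <- c("rt_schedule", "data.frame")
  out
}

#' Coerce to a schedule
#' @param x A data frame with columns `time_days` and `dose_gy`, or an
#'   `rt_schedule`.
#' @param ... Unused.
#' @return An `rt_schedule`.
#' @export
as_schedule <- function(x, ...) {
  if (inherits(x, "rt_schedule")) return(x)
  if (is.data.frame(x) && all(c("time_days", "dose_gy") %in% names(x)))
    return(schedule(x$time_days, x$dose_gy))
  stop("cannot coerce to a schedule: need columns time_days, dose_gy",
       call. = FALSE)
}

#' Number of irradiation events in a schedule
#' @param x An `rt_schedule`.
#' @return Integer event count N.
#' @export
n_events <- function(x) nrow(as_schedule(x))

#' @export
print.rt_schedule <- function(x, ...) {
  cat(sprintf("Radiotherapy schedule: %d event(s), %g Gy total, span %g d\n",
              nrow(x), sum(x$dose_gy), max(x$time_days) - min(x$time_days)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Uniformly spaced course
#'
#' `n` equal fractions of `dose` Gy separated by `interval` days, starting at
#' `start`.
#'
#' @param n Number of fractions (>= 1).
#' @param dose Dose per fraction, Gy (> 0).
#' @param interval Interfraction interval, days (> 0).
#' @param start Time of the first fraction, days (default 0).
#' @return An `rt_schedule`.
#' @examples
#' schedule_uniform(3, 8)   # 8 Gy on days 0, 1, 2
#' schedule_uniform(5, 6)   # 6 Gy on days 0..4
#' @export
schedule_uniform <- function(n, dose, interval = 1, start = 0) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive whole number", call. = FALSE)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("`interval` must be a positive number of days", call. = FALSE)
  schedule(start + (seq_len(n) - 1L) * interval, dose)
}

# 0-based calendar days of the first n weekday slots; day 0 is a
# Monday-equivalent, days 5 and 6 of each week are the weekend gap.
weekday_slots <- function(n, start = 0) {
  k <- seq_len(n) - 1L
  start + 7 * (k %/% 5) + k %% 5
}

#' Weekday (normofractionated-style) course
#'
#' One fraction per weekday: five consecutive treatment days, then a two-day
#' weekend gap, repeating. Day 0 is a Monday-equivalent, so 25 fractions span
#' days 0 through 32 (5 treatment weeks).
#'
#' @param n_fractions Number of fractions (>= 1).
#' @param dose Dose per fraction, Gy (default 2).
#' @param start Day of the first fraction (default 0, a Monday-equivalent).
#' @return An `rt_schedule`.
#' @examples
#' schedule_weekday(25, 2)   # 50 Gy in 25 fractions over 32 days
#' schedule_weekday(6, 2)    # days 0-4, then 7
#' @export
schedule_weekday <- function(n_fractions, dose = 2, start = 0) {
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L ||
      n_fractions < 1 || n_fractions != round(n_fractions))
    stop("`n_fractions` must be a positive whole number", call. = FALSE)
  schedule(weekday_slots(n_fractions, start), dose)
}

#' Define a block of treatment days
#'
#' A segment is a contiguous block of `n_days` treatment days starting on
#' `start_day`, each day carrying the same within-day fraction pattern:
#' one or more fractions at hour offsets `offset_hours` with doses `dose_gy`
#' (bifractionation is two entries, e.g. offsets 0 and 6 h). With
#' `weekdays_only`, treatment days skip weekend days of the global calendar
#' (day 0 = Monday-equivalent) while still delivering `n_days` treatment days.
#'
#' @param start_day First treatment day (days from course start).
#' @param n_days Number of treatment days (>= 1).
#' @param dose_gy Doses of the within-day fractions, Gy.
#' @param offset_hours Hour offsets of the within-day fractions, strictly
#'   increasing, within one day (default 0 for a single daily fraction).
#' @param weekdays_only Skip weekend calendar days (default FALSE).
#' @return An object of class `rt_segment`.
#' @examples
#' rt_segment(0, 1, c(2, 2), c(0, 6))     # one bifractionated (2+2) day
#' rt_segment(14, 10, 2, weekdays_only = TRUE)  # two normofractionated weeks
#' @export
rt_segment <- function(start_day, n_days, dose_gy, offset_hours = 0,
                       weekdays_only = FALSE) {
  if (length(dose_gy) < 1L)
    stop("a segment needs at least one within-day fraction", call. = FALSE)
  if (length(offset_hours) == 1L && length(dose_gy) > 1L && offset_hours == 0)
    stop("give one `offset_hours` per within-day fraction", call. = FALSE)
  if (length(offset_hours) != length(dose_gy))
    stop("`offset_hours` and `dose_gy` must have the same length", call. = FALSE)
  if (any(diff(offset_hours) <= 0) && length(offset_hours) > 1L)
    stop("`offset_hours` must be strictly increasing", call. = FALSE)
  if (any(offset_hours < 0) || any(offset_hours >= 24))
    stop("`offset_hours` must lie within one day [0, 24)", call. = FALSE)
  if (!is.numeric(n_days) || n_days < 1 || n_days != round(n_days))
    stop("`n_days` must be a positive whole number", call. = FALSE)
  if (any(dose_gy <= 0)) stop("segment doses must be positive", call. = FALSE)
  structure(list(start_day = start_day, n_days = as.integer(n_days),
                 dose_gy = as.numeric(dose_gy),
                 offset_hours = as.numeric(offset_hours),
                 weekdays_only = isTRUE(weekdays_only)),
            class = "rt_segment")
}

segment_days <- function(seg) {
  if (!seg$weekdays_only) return(seg$start_day + seq_len(seg$n_days) - 1L)
  days <- integer(0)
  d <- seg$start_day
  while (length(days) < seg$n_days) {
    if (d %% 7 < 5) days <- c(days, d)
    d <- d + 1L
  }
  days
}

#' Compose segments into a schedule
#'
#' Expands each segment into its irradiation events and merges them into one
#' time-sorted schedule. Events at identical times (across or within
#' segments) are merged with a warning into one event with the summed dose.
#'
#' @param ... `rt_segment` objects, or a single list of them.
#' @return An `rt_schedule`.
#' @examples
#' # one bifractionated day, a 10-day break, then a normofractionated week
#' compose_segments(
#'   rt_segment(0, 1, c(2, 2), c(0, 6)),
#'   rt_segment(11, 5, 2)
#' )
#' @export
compose_segments <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1L]]) &&
      !inherits(segs[[1L]], "rt_segment"))
    segs <- segs[[1L]]
  if (length(segs) == 0L)
    stop("at least one segment is required", call. = FALSE)
  ok <- vapply(segs, inherits, logical(1), "rt_segment")
  if (!all(ok)) stop("all arguments must be rt_segment objects", call. = FALSE)
  times <- unlist(lapply(segs, function(s) {
    outer(segment_days(s), s$offset_hours / 24, `+`)
  }))
  doses <- unlist(lapply(segs, function(s) {
    rep(s$dose_gy, each = s$n_days)
  }))
  if (anyDuplicated(round(times / 1e-9)))
    warning("coincident events across segments merged (doses summed)",
            call. = FALSE)
  schedule(times, doses)
}

#' Parse a compact schedule specification
#'
#' The grammar accepts terms joined by `;`:
#' \describe{
#'   \item{`<n>x<dose>Gy@<interval>d[+offset]`}{`n` fractions of `dose` Gy
#'     every `interval` days, starting at day `offset` (default 0); e.g.
#'     `"3x8Gy@1d"` or `"2x6Gy@1d+10"`.}
#'   \item{`(t,d)`}{an explicit event at time `t` days with dose `d` Gy;
#'     e.g. `"(0,2);(0.25,2)"`.}
#' }
#'
#' @param text The specification string.
#' @return An `rt_schedule`.
#' @examples
#' parse_schedule("3x8Gy@1d")
#' parse_schedule("3x8Gy@1d;2x6Gy@1d+10")
#' parse_schedule("(0,2);(0.25,2)")
#' @export
parse_schedule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("schedule spec is empty or not a string", call. = FALSE)
  num <- "[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?"
  re_course <- sprintf("^([0-9]+)x(%s)Gy@(%s)d(?:\\+(%s))?$", num, num, num)
  re_event <- sprintf("^\\((%s),(%s)\\)$", num, num)
  terms <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  times <- numeric(0); doses <- numeric(0)
  for (term in terms) {
    if (grepl(re_course, term)) {
      m <- regmatches(term, regexec(re_course, term))[[1L]]
      n <- as.integer(m[2L]); dose <- as.numeric(m[3L])
      interval <- as.numeric(m[4L])
      offset <- if (nzchar(m[5L])) as.numeric(m[5L]) else 0
      if (interval <= 0)
        stop(sprintf("schedule spec term '%s': interval must be positive", term),
             call. = FALSE)
      times <- c(times, offset + (seq_len(n) - 1L) * interval)
      doses <- c(doses, rep(dose, n))
    } else if (grepl(re_event, term)) {
      m <- regmatches(term, regexec(re_event, term))[[1L]]
      times <- c(times, as.numeric(m[2L]))
      doses <- c(doses, as.numeric(m[3L]))
    } else {
      stop(sprintf("cannot parse schedule spec term '%s'", term), call. = FALSE)
    }
  }
  schedule(times, doses)
}

#' Format a schedule as a compact specification string
#'
#' Produces an explicit `(t,d)` event list that [parse_schedule()] reads back
#' losslessly.
#'
#' @param x An `rt_schedule`.
#' @return A single string.
#' @examples
#' format_schedule(schedule_uniform(3, 8))
#' @export
format_schedule <- function(x) {
  x <- as_schedule(x)
  paste(sprintf("(%s,%s)", format(x$time_days, digits = 17, trim = TRUE),
                format(x$dose_gy, digits = 17, trim = TRUE)),
        collapse = ";")
}

#' Read and write schedules
#'
#' CSV files carry a header `time_days,dose_gy` (comma-separated, dot
#' decimal); JSON files carry `{"events": [{"time_days": ..., "dose_gy":
#' ...}, ...]}`. Events are sorted on read; round-trips preserve full float
#' precision.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (from the file extension).
#' @return `read_schedule` returns an `rt_schedule`; `write_schedule`
#'   invisibly returns `path`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_schedule(schedule_uniform(3, 8), p)
#' read_schedule(p)
#' @export
read_schedule <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
    if (!all(c("time_days", "dose_gy") %in% names(df)))
      stop("CSV schedule must have columns time_days, dose_gy", call. = FALSE)
    t <- suppressWarnings(as.numeric(df$time_days))
    d <- suppressWarnings(as.numeric(df$dose_gy))
    bad <- which(is.na(t) | is.na(d) | t < 0 | d <= 0)
    if (length(bad))
      stop(sprintf("invalid schedule value(s) at data row %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    schedule(t, d)
  } else {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (is.null(doc$events))
      stop("JSON schedule must contain an 'events' array", call. = FALSE)
    ev <- as.data.frame(doc$events)
    if (!all(c("time_days", "dose_gy") %in% names(ev)))
      stop("JSON events need fields time_days and dose_gy", call. = FALSE)
    schedule(ev$time_days, ev$dose_gy)
  }
}

#' @rdname read_schedule
#' @param x An `rt_schedule` to write.
#' @export
write_schedule <- function(x, path, format = c("auto", "csv", "json")) {
  x <- as_schedule(x)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- data.frame(time_days = format(x$time_days, digits = 17, trim = TRUE),
                     dose_gy = format(x$dose_gy, digits = 17, trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(events = data.frame(time_days = x$time_days, dose_gy = x$dose_gy)),
      path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
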