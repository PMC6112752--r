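#' IED efficacy as a function of interfraction time
#'
#' Evaluates a uniform course of `n_doses` fractions of `dose` Gy for each
#' interfraction gap on a grid, tracing how the timing alone reshapes the
#' immunogenicity. For two fractions the characteristic shape is a steep
#' drop once the gap exceeds T_D (the second fraction kills the recruited
#' immune effectors) followed by a shallower recovery once the gap exceeds
#' roughly T_D + T_IR (the activation has completed before the second hit).
#'
#' @param dose Dose per fraction, Gy.
#' @param n_doses Number of fractions (>= 1; with 1 the curve is constant).
#' @param gap_min,gap_max Smallest and largest interfraction gap, days
#'   (0 < gap_min < gap_max).
#' @param n_points Number of grid points (>= 2), spaced uniformly.
#' @param params An [rt_params] object.
#' @param kinetics An [immune_kinetics] object.
#' @return An object of class `ied_sweep`: a data frame with columns
#'   `gap_days` and `efficacy`, with the parameters attached as attributes.
#' @examples
#' sw <- interfraction_sweep(2, 2, 0.25, 21, n_points = 30)
#' head(sw)
#' @export
interfraction_sweep <- function(dose, n_doses = 2, gap_min = 0.25,
                                gap_max = 21, n_points = 50,
                                params = rt_params(),
                                kinetics = immune_kinetics()) {
  if (gap_min <= 0 || gap_max <= gap_min)
    stop("need 0 < gap_min < gap_max", call. = FALSE)
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  gaps <- seq(gap_min, gap_max, length.out = n_points)
  eff <- vapply(gaps, function(gap) {
    ied_efficacy(schedule_uniform(n_doses, dose, interval = gap),
                 params, kinetics)
  }, numeric(1))
  out <- data.frame(gap_days = gaps, efficacy = eff)
  attr(out, "dose") <- dose
  attr(out, "n_doses") <- n_doses
  attr(out, "params") <- params
  attr(out, "kinetics") <- kinetics
  class(out) <- c("ied_sweep", "data.frame")
  out
}

#' @export
print.ied_sweep <- function(x, ...) {
  cat(sprintf("Interfraction-time sweep: %d x %g Gy, gaps %g-%g d (%d points)\n",
              attr(x, "n_doses"), attr(x, "dose"),
              min(x$gap_days), max(x$gap_days), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.ied_sweep <- function(x, ...) {
  graphics::plot(x$gap_days, 100 * x$efficacy, type = "l",
                 xlab = "Interfraction time (days)",
                 ylab = "IED efficacy (%)",
                 main = sprintf("%d x %g Gy", attr(x, "n_doses"),
                                attr(x, "dose")), ...)
  invisible(x)
}

#' Compare schedules on all dose metrics
#'
#' Evaluates each schedule and tabulates EQD2, BED and IED efficacy side by
#' side, one row per schedule. `efficacy_pct` carries the whole-percent
#' rounding used in reports; `ied_efficacy` keeps full precision.
#'
#' @param schedules A named list of `rt_schedule` objects (names become row
#'   labels; unnamed entries are labelled by position).
#' @param params An [rt_params] object.
#' @param kinetics An [immune_kinetics] object.
#' @return A data frame with columns `label`, `alpha`, `alpha_beta`,
#'   `eqd2_gy`, `bed_gy`, `ied_efficacy`, `efficacy_pct`.
#' @examples
#' compare_schedules(list("3x8" = schedule_uniform(3, 8),
#'                        "5x6" = schedule_uniform(5, 6)))
#' @export
compare_schedules <- function(schedules, params = rt_params(),
                              kinetics = immune_kinetics()) {
  if (inherits(schedules, "rt_schedule")) schedules <- list(schedules)
  if (length(schedules) < 1L)
    stop("at least one schedule is required", call. = FALSE)
  labels <- names(schedules)
  if (is.null(labels)) labels <- rep("", length(schedules))
  labels[!nzchar(labels)] <-
    paste0("schedule_", seq_along(schedules))[!nzchar(labels)]
  rows <- lapply(seq_along(schedules), function(i) {
    r <- ied_evaluate(schedules[[i]], params, kinetics, include_theta = FALSE)
    data.frame(label = labels[i], alpha = params$alpha,
               alpha_beta = params$alpha_beta,
               eqd2_gy = r$eqd2_gy, bed_gy = r$bed_gy,
               ied_efficacy = r$efficacy,
               efficacy_pct = round(100 * r$efficacy))
  })
  do.call(rbind, rows)
}

#' Enumerate candidate hybrid schedules on a discrete grid
#'
#' Generates the discretized family of split/bifractionated courses used by
#' [constrained_search()]: an optional leading block of `lead_days`
#' bifractionated days (two fractions of `lead_dose` Gy, 6 h apart), a break
#' of a whole number of days, a middle block of bifractionated (2+2) days,
#' and a normofractionated 2 Gy weekday tail, plus the plain weekday course
#' itself. Doses come from `dose_grid`, breaks are whole days, and the
#' bifractionation offset is fixed at 0.25 d. The grid is small by design:
#' it contains the classic course and the split/bifractionated patterns of
#' practical interest while remaining exhaustively enumerable.
#'
#' @param dose_grid Candidate doses per fraction for the leading block, Gy.
#' @param lead_days_grid Candidate lengths of the leading block, days.
#' @param break_grid Candidate break lengths, whole days.
#' @param mid_days_grid Candidate lengths of the middle bifractionated
#'   block, days.
#' @param tail_fractions Number of 2 Gy weekday fractions in the tail.
#' @param reference_fractions Fractions in the plain weekday reference
#'   course included alongside the hybrids (default 25).
#' @return A named list of `rt_schedule` objects.
#' @export
hybrid_candidates <- function(dose_grid = c(2, 3),
                              lead_days_grid = 1:2,
                              break_grid = c(10, 13),
                              mid_days_grid = c(5, 9),
                              tail_fractions = 10,
                              reference_fractions = 25) {
  cands <- list()
  cands[[sprintf("weekday_%dx2Gy", reference_fractions)]] <-
    schedule_weekday(reference_fractions, 2)
  for (d in dose_grid) for (ld in lead_days_grid) for (br in break_grid)
    for (md in mid_days_grid) {
      mid_start <- ld + br
      tail_start <- mid_start + md + 1
      # align the tail to the next Monday-equivalent so weekday slots exist
      tail_start <- tail_start + (7 - tail_start %% 7) %% 7
      s <- compose_segments(
        rt_segment(0, ld, c(d, d), c(0, 6)),
        rt_segment(mid_start, md, c(2, 2), c(0, 6)),
        rt_segment(tail_start, tail_fractions, 2, weekdays_only = TRUE)
      )
      nm <- sprintf("bifrac%dd_%gGy_break%d_mid%d", ld, d, br, md)
      cands[[nm]] <- s
    }
  cands
}

#' Search a candidate set for the most immunogenic feasible schedule
#'
#' Exhaustively evaluates every candidate, keeps those meeting the hard
#' constraints, and ranks the survivors by IED efficacy (descending). Ties
#' are broken lexicographically on the event list so the ranking is fully
#' reproducible.
#'
#' @param candidates A named list of `rt_schedule` objects, e.g. from
#'   [hybrid_candidates()].
#' @param constraints A list with any of: `bed` (length-2 numeric range,
#'   Gy), `eqd2` (range, Gy), `max_span` (days), `max_dose` (Gy per
#'   fraction). Missing entries are unconstrained.
#' @param params An [rt_params] object.
#' @param kinetics An [immune_kinetics] object.
#' @param top_k Keep at most this many ranked schedules (default all).
#' @return A data frame (one row per feasible candidate, best first) with
#'   columns `label`, `eqd2_gy`, `bed_gy`, `span_days`, `max_dose_gy`,
#'   `ied_efficacy`, `efficacy_pct`, and the schedules themselves in the
#'   `schedule` list-column. Zero feasible candidates yield an empty data
#'   frame and a message.
#' @export
constrained_search <- function(candidates, constraints = list(),
                               params = rt_params(),
                               kinetics = immune_kinetics(),
                               top_k = Inf) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  labels <- names(candidates)
  if (is.null(labels)) labels <- paste0("candidate_", seq_along(candidates))
  feas <- list()
  for (i in seq_along(candidates)) {
    s <- as_schedule(candidates[[i]])
    span <- max(s$time_days) - min(s$time_days)
    b <- bed(s, params); e2 <- eqd2(s, params); dmax <- max(s$dose_gy)
    ok <- TRUE
    if (!is.null(constraints$bed))
      ok <- ok && b >= constraints$bed[1] && b <= constraints$bed[2]
    if (!is.null(constraints$eqd2))
      ok <- ok && e2 >= constraints$eqd2[1] && e2 <= constraints$eqd2[2]
    if (!is.null(constraints$max_span))
      ok <- ok && span <= constraints$max_span
    if (!is.null(constraints$max_dose))
      ok <- ok && dmax <= constraints$max_dose
    if (!ok) next
    eff <- ied_efficacy(s, params, kinetics)
    feas[[length(feas) + 1L]] <- list(
      label = labels[i], eqd2_gy = e2, bed_gy = b, span_days = span,
      max_dose_gy = dmax, ied_efficacy = eff, schedule = s,
      key = format_schedule(s))
  }
  if (length(feas) == 0L) {
    message("constrained_search: no candidate satisfies the constraints")
    return(data.frame(label = character(0), eqd2_gy = numeric(0),
                      bed_gy = numeric(0), span_days = numeric(0),
                      max_dose_gy = numeric(0), ied_efficacy = numeric(0),
                      efficacy_pct = numeric(0)))
  }
  eff <- vapply(feas, `[[`, numeric(1), "ied_efficacy")
  key <- vapply(feas, `[[`, character(1), "key")
  ord <- order(-eff, key, method = "radix")
  feas <- feas[ord][seq_len(min(top_k, length(feas)))]
  out <- data.frame(
    label = vapply(feas, `[[`, character(1), "label"),
    eqd2_gy = vapply(feas, `[[`, numeric(1), "eqd2_gy"),
    bed_gy = vapply(feas, `[[`, numeric(1), "bed_gy"),
    span_days = vapply(feas, `[[`, numeric(1), "span_days"),
    max_dose_gy = vapply(feas, `[[`, numeric(1), "max_dose_gy"),
    ied_efficacy = vapply(feas, `[[`, numeric(1), "ied_efficacy"))
  out$efficacy_pct <- round(100 * out$ied_efficacy)
  out$schedule <- lapply(feas, `[[`, "schedule")
  out
}

#' Write a comparison table or sweep to TSV or JSON
#'
#' Machine formats carry full precision; list-columns (schedules) are
#' rendered as compact spec strings in TSV and as event arrays in JSON.
#'
#' @param x A data frame (e.g. from [compare_schedules()],
#'   [constrained_search()]) or an `ied_sweep`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"` (default from the extension).
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  df <- as.data.frame(x)
  if (!is.null(df$schedule))
    df$schedule <- vapply(df$schedule, format_schedule, character(1))
  if (format == "tsv") {
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       file = path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
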