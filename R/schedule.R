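# Treatment calendar: weekday fractions, weekend gaps, optional treatment
# interruptions, daily imaging on fraction days.

is_weekday <- function(date) {
  # POSIXlt wday: 0 = Sunday ... 6 = Saturday
  wd <- as.POSIXlt(date)$wday
  wd >= 1L & wd <= 5L
}

#' Build a standard fractionated treatment course
#'
#' Lays out `n_fractions` daily 2 Gy fractions on consecutive weekdays from
#' `start_date` (weekends untreated), with an optional treatment
#' interruption: after `gap_after_fraction` delivered fractions the next
#' `gap_weekdays` weekdays are skipped before treatment resumes. Imaging
#' (cone-beam CT) is flagged on every fraction day. The course covers every
#' calendar day from the first to the last fraction, untreated days
#' included.
#'
#' A one-week interruption of `gap_weekdays = 5` shifts the remaining
#' calendar by exactly 7 days; `gap_weeks` is shorthand for
#' `gap_weekdays = 5 * gap_weeks`.
#'
#' @param start_date First fraction day (a `Date` or something coercible);
#'   must be a weekday.
#' @param n_fractions Number of fractions (33 in a 66 Gy course).
#' @param gap_weeks Whole treatment weeks missed (0 for none).
#' @param gap_after_fraction Number of fractions delivered before the
#'   interruption starts.
#' @param gap_weekdays Weekdays missed; overrides `gap_weeks` when given.
#' @return A tibble of class `treatment_course` with one row per calendar
#'   day: `date`, `day` (0-based index from the first fraction), `fraction`
#'   (logical), `dose` (Gy, 2 on fraction days), `imaging` (logical),
#'   `volume_cm3` (`NA` until measured).
#' @examples
#' crs <- standard_course(as.Date("2017-01-02"), n_fractions = 33)
#' nrow(crs)  # 45-day span for a Monday start
#' @export
standard_course <- function(start_date, n_fractions = 33, gap_weeks = 0,
                            gap_after_fraction = 5, gap_weekdays = NULL) {
  start_date <- as.Date(start_date)
  if (is.na(start_date)) abort("`start_date` is not a date.",
                               class = "csck_config_error")
  if (!is_weekday(start_date)) {
    abort("`start_date` falls on a weekend; fractions are weekday-only.",
          class = "csck_config_error")
  }
  stopifnot(n_fractions >= 1, gap_weeks >= 0, gap_after_fraction >= 1)
  if (is.null(gap_weekdays)) gap_weekdays <- 5L * gap_weeks
  fraction_dates <- as.Date(character(0))
  d <- start_date
  delivered <- 0L
  to_skip <- 0L
  while (delivered < n_fractions) {
    if (is_weekday(d)) {
      if (to_skip > 0L) {
        to_skip <- to_skip - 1L
      } else {
        fraction_dates <- c(fraction_dates, d)
        delivered <- delivered + 1L
        if (delivered == gap_after_fraction) to_skip <- as.integer(gap_weekdays)
      }
    }
    d <- d + 1L
  }
  dates <- seq(min(fraction_dates), max(fraction_dates), by = "day")
  fraction <- dates %in% fraction_dates
  course <- tibble::tibble(
    date = dates,
    day = as.integer(dates - dates[1L]),
    fraction = fraction,
    dose = ifelse(fraction, 2, 0),
    imaging = fraction,
    volume_cm3 = NA_real_
  )
  new_treatment_course(course)
}

new_treatment_course <- function(course) {
  class(course) <- c("treatment_course", class(course))
  course
}

validate_course <- function(course) {
  needed <- c("date", "day", "fraction", "imaging", "volume_cm3")
  if (!is.data.frame(course) || !all(needed %in% names(course))) {
    abort(paste("A treatment course needs columns:",
                paste(needed, collapse = ", ")),
          class = "csck_config_error")
  }
  if (nrow(course) == 0L) {
    abort("Empty treatment course.", class = "csck_config_error")
  }
  if (any(diff(as.integer(course$day)) != 1L)) {
    abort("Course days must be contiguous calendar days.",
          class = "csck_config_error")
  }
  vols <- course$volume_cm3
  if (any(!is.na(vols) & vols <= 0)) {
    abort("Measured volumes must be positive.", class = "csck_config_error")
  }
  invisible(course)
}

#' Simulate the kinetic model over a treatment course
#'
#' Runs the analytic daily update across a treatment calendar. The initial
#' state on the first fraction day is `(U, V, W) = (p, 1 - p, 0)`, so the
#' total count starts at 1; the state on day `i` is the pre-treatment state
#' of that day, and the transition from day `i` to `i + 1` uses day `i`'s
#' fraction flag. Because tumor volume is assumed proportional to the total
#' clonogen count, the normalized total `total_norm = G_i / G_0` is the
#' model's prediction of relative imaged volume.
#'
#' @param params A [kinetic_parameters()] object.
#' @param course A `treatment_course` tibble, e.g. from [standard_course()].
#' @param legacy Use legacy sign conventions? See [step_coefficients()].
#' @return The course tibble with columns `U`, `V`, `W`, `total` and
#'   `total_norm` appended.
#' @examples
#' pars <- kinetic_parameters(0.024, 0.242, T_u = 6.2, T_h = 1.1,
#'                            SF_u = 0.980, SF_v = 0.874)
#' sim <- simulate_course(pars, standard_course(as.Date("2017-01-02")))
#' tail(sim$total_norm, 1)  # residual relative burden at course end
#' @export
simulate_course <- function(params, course, legacy = FALSE) {
  validate_kinetic_parameters(params)
  validate_course(course)
  flags <- course$fraction
  n <- nrow(course)
  Pt <- day_propagator(params, treated = TRUE, legacy = legacy)
  Pu <- day_propagator(params, treated = FALSE, legacy = legacy)
  states <- matrix(NA_real_, nrow = n, ncol = 3L)
  s <- c(params$p, 1 - params$p, 0)
  states[1L, ] <- s
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      s <- drop((if (flags[i]) Pt else Pu) %*% s)
      states[i + 1L, ] <- s
    }
  }
  out <- course
  out$U <- states[, 1L]
  out$V <- states[, 2L]
  out$W <- states[, 3L]
  out$total <- rowSums(states)
  out$total_norm <- out$total / out$total[1L]
  out
}

#' Read / write a treatment-course file
#'
#' The on-disk dialect is a CSV with header `date,fraction,volume_cm3`
#' (ISO-8601 dates, `fraction` in `{0, 1}`, `volume_cm3` empty when no
#' imaging was done). A JSON array of objects with the same fields is
#' accepted and produced when the path ends in `.json`.
#'
#' @param path File path (`.csv` or `.json`).
#' @return `read_course()` returns a `treatment_course` tibble;
#'   `write_course()` invisibly returns `path`.
#' @export
read_course <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "csck_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("date", "fraction", "volume_cm3")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Course file %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "csck_parse_error")
  }
  dates <- tryCatch(as.Date(raw$date),
                    error = function(e) rep(as.Date(NA), nrow(raw)))
  if (anyNA(dates)) {
    abort(sprintf("Unparseable date at line %d of %s.",
                  which(is.na(dates))[1L] + 1L, path),
          class = "csck_parse_error")
  }
  course <- tibble::tibble(
    date = dates,
    day = as.integer(dates - dates[1L]),
    fraction = as.integer(raw$fraction) == 1L,
    dose = ifelse(as.integer(raw$fraction) == 1L, 2, 0),
    imaging = !is.na(as.numeric(raw$volume_cm3)),
    volume_cm3 = as.numeric(raw$volume_cm3)
  )
  validate_course(course)
  new_treatment_course(course)
}

#' @rdname read_course
#' @param course A `treatment_course` tibble.
#' @export
write_course <- function(course, path) {
  validate_course(course)
  out <- data.frame(
    date = format(course$date, "%Y-%m-%d"),
    fraction = as.integer(course$fraction),
    volume_cm3 = course$volume_cm3
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Extract the measured-volume series from a course
#'
#' @param course A `treatment_course` tibble with measured volumes.
#' @return A tibble `(date, day, volume_cm3)`, one row per imaging day with
#'   a measurement.
#' @export
volume_series <- function(course) {
  validate_course(course)
  out <- course[!is.na(course$volume_cm3), c("date", "day", "volume_cm3")]
  tibble::as_tibble(out)
}
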