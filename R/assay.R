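# Clonogenic-style growth assay: exponential fits to cell-count time
# courses, day-0 extrapolation, surviving fraction at 2 Gy and division
# time.

#' Build a cell-count series
#'
#' @param day Strictly increasing counting days (day 0 = seeding).
#' @param count_millions Mean counts in millions (replicates averaged).
#' @param irradiated Logical: was this arm irradiated (2 Gy) after plating?
#' @param seed_millions Optional seeded cell count at day 0, millions.
#' @return A tibble `(day, count_millions, irradiated)` with a
#'   `seed_millions` attribute.
#' @export
cell_count_series <- function(day, count_millions, irradiated = FALSE,
                              seed_millions = NULL) {
  if (length(day) != length(count_millions) || length(day) < 2L) {
    abort("Need at least two (day, count) pairs of equal length.",
          class = "csck_config_error")
  }
  if (any(diff(day) <= 0)) {
    abort("Days must be strictly increasing.", class = "csck_config_error")
  }
  if (any(count_millions <= 0)) {
    abort("Counts must be positive.", class = "csck_config_error")
  }
  out <- tibble::tibble(day = as.numeric(day),
                        count_millions = as.numeric(count_millions),
                        irradiated = rep(as.logical(irradiated),
                                         length.out = length(day)))
  attr(out, "seed_millions") <- seed_millions
  out
}

#' Per-day count ratios between an irradiated and a control arm
#'
#' Ratios `N_irr / N_ctrl` on the days present in both series. Because the
#' irradiated arm repopulates more slowly, the ratio keeps decreasing with
#' time, which is why the surviving fraction must be read off at day 0 by
#' extrapolation rather than from any single counting day.
#'
#' @param irradiated,control Tibbles `(day, count_millions)` (e.g. from
#'   [cell_count_series()] or the two arms of [assay_counts()]).
#' @param digits Rounding for the reported ratio (default 2, as usually
#'   reported); `NULL` for no rounding.
#' @return A tibble `(day, n_irradiated, n_control, ratio)`.
#' @examples
#' a <- assay_counts()
#' count_ratios(a[a$irradiated, ], a[!a$irradiated, ])
#' @export
count_ratios <- function(irradiated, control, digits = 2) {
  shared <- dplyr::inner_join(
    dplyr::select(irradiated, day = "day", n_irradiated = "count_millions"),
    dplyr::select(control, day = "day", n_control = "count_millions"),
    by = "day"
  )
  if (nrow(shared) == 0L) {
    abort("The two series share no counting day.", class = "csck_config_error")
  }
  ratio <- shared$n_irradiated / shared$n_control
  if (!is.null(digits)) ratio <- round(ratio, digits)
  dplyr::mutate(shared, ratio = ratio)
}

#' Fit an exponential growth curve to a count series
#'
#' Fits `N(t) = N0 * exp(k * t)` either by ordinary least squares on the
#' log counts (default: the classic exponential-trendline extrapolation,
#' which weights every counting day equally and reproduces reported day-0
#' extrapolates of this assay type) or by nonlinear least squares on the
#' raw counts (`method = "nls"`, which the late large counts dominate).
#' The seeded day-0 count, when available, can be included as a data point
#' (default: included, the convention used for the unirradiated control
#' arm).
#'
#' @param series A tibble `(day, count_millions)`; replicate-level input is
#'   averaged by day first.
#' @param seed_millions Day-0 seeded count to include; defaults to the
#'   series' `seed_millions` attribute.
#' @param include_seed Include the day-0 point? Default: yes, when a seed
#'   count is known.
#' @param method `"loglinear"` (OLS on log counts, the default) or
#'   `"nls"` (nonlinear LS on counts).
#' @return An object of class `growth_fit`: list with `N0` (extrapolated
#'   day-0 count, millions), `k` (growth rate per day), `doubling_days`
#'   (`log(2)/k`), `resid_norm`, `method`, `data`.
#' @examples
#' a <- assay_counts()
#' fit_exponential(a[!a$irradiated, ], seed_millions = 1.6)
#' @export
fit_exponential <- function(series, seed_millions = NULL,
                            include_seed = !is.null(seed_millions) ||
                              !is.null(attr(series, "seed_millions")),
                            method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (is.null(seed_millions)) seed_millions <- attr(series, "seed_millions")
  dat <- dplyr::summarise(dplyr::group_by(series, .data$day),
                          count = mean(.data$count_millions), .groups = "drop")
  if (include_seed) {
    if (is.null(seed_millions)) {
      abort("`include_seed = TRUE` but no seed count is known.",
            class = "csck_config_error")
    }
    dat <- dplyr::bind_rows(tibble::tibble(day = 0, count = seed_millions),
                            dat)
    dat <- dat[!duplicated(dat$day), ]
  }
  if (nrow(dat) < 2L) {
    abort("Need at least two points to fit an exponential.",
          class = "csck_config_error")
  }
  # log-linear solution: exact when the data lie on an exponential, and
  # the start value (or the fit itself for method = "loglinear")
  ll <- lm(log(count) ~ day, data = dat)
  N0_ll <- exp(coef(ll)[[1L]])
  k_ll <- coef(ll)[[2L]]
  if (method == "loglinear") {
    N0 <- N0_ll; k <- k_ll
    rn <- sqrt(sum((dat$count - N0 * exp(k * dat$day))^2))
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(count ~ N0 * exp(k * day), data = dat,
                        start = list(N0 = N0_ll, k = k_ll),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning("Nonlinear fit did not converge; falling back to the ",
              "log-linear solution.")
      N0 <- N0_ll; k <- k_ll
    } else {
      N0 <- coef(fit)[["N0"]]; k <- coef(fit)[["k"]]
    }
    rn <- sqrt(sum((dat$count - N0 * exp(k * dat$day))^2))
  }
  if (N0 <= 0) {
    abort("Fitted day-0 count is non-positive.", class = "csck_fit_error")
  }
  structure(list(N0 = N0, k = k,
                 doubling_days = if (k > 0) log(2) / k else NA_real_,
                 resid_norm = rn, method = method,
                 include_seed = include_seed, data = dat),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit>  N(t) = %.4g * exp(%.4g t)   [%s%s]\n",
              x$N0, x$k, x$method,
              if (x$include_seed) ", seed included" else ""))
  if (is.finite(x$doubling_days)) {
    cat(sprintf("  doubling time %.3g d (%.1f h); residual norm %.3g\n",
                x$doubling_days, 24 * x$doubling_days, x$resid_norm))
  }
  invisible(x)
}

#' Surviving fraction from paired growth fits
#'
#' The surviving fraction after the single dose is the ratio of the
#' extrapolated day-0 counts of the irradiated and control arms,
#' `SF = N0_irr / N0_ctrl` — i.e. the count ratio freed from the
#' confounding effect of repopulation.
#'
#' @param irradiated_fit,control_fit `growth_fit` objects (or numeric day-0
#'   counts).
#' @return The surviving fraction, a scalar.
#' @examples
#' surviving_fraction(1.344, 1.476)  # ~0.91
#' @export
surviving_fraction <- function(irradiated_fit, control_fit) {
  n0 <- function(f) if (inherits(f, "growth_fit")) f$N0 else as.numeric(f)
  n_irr <- n0(irradiated_fit); n_ctrl <- n0(control_fit)
  if (!is.finite(n_ctrl) || n_ctrl <= 0) {
    abort("Control day-0 count must be positive.", class = "csck_domain_error")
  }
  n_irr / n_ctrl
}

#' Cell division time from a growth rate
#'
#' @param k Exponential growth rate per day, `> 0`.
#' @return A tibble `(days, hours)` with `days = log(2) / k`.
#' @examples
#' division_time(0.2865)  # ~2.42 d, ~58.1 h
#' @export
division_time <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive rate (per day).",
          class = "csck_domain_error")
  }
  d <- log(2) / k
  tibble::tibble(days = d, hours = 24 * d)
}

#' Read an assay CSV
#'
#' Dialect: columns `day`, `count_millions`, `irradiated` (0/1 or
#' TRUE/FALSE); the seeded day-0 count may be given in an optional
#' `seed_millions` column (constant) or passed explicitly.
#'
#' @param path CSV path.
#' @param seed_millions Seed count override.
#' @return A tibble `(day, count_millions, irradiated)` with attribute
#'   `seed_millions`.
#' @export
read_assay <- function(path, seed_millions = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("day", "count_millions", "irradiated")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("Assay file %s needs columns: %s", path,
                  paste(needed, collapse = ", ")),
          class = "csck_parse_error")
  }
  if (is.null(seed_millions) && "seed_millions" %in% names(raw)) {
    seed_millions <- raw$seed_millions[1L]
  }
  out <- tibble::tibble(day = as.numeric(raw$day),
                        count_millions = as.numeric(raw$count_millions),
                        irradiated = as.logical(as.integer(raw$irradiated)))
  attr(out, "seed_millions") <- seed_millions
  out
}

#' Full survival-assay analysis
#'
#' Runs the complete analysis of a two-arm growth assay: per-day count
#' ratios, exponential fits per arm (seed point included for the control
#' arm by default), day-0 extrapolation, surviving fraction and division
#' time.
#'
#' @param counts A tibble `(day, count_millions, irradiated)`; defaults to
#'   the packaged NCI-H2170 assay ([assay_counts()]).
#' @param seed_millions Seeded count at day 0, millions.
#' @param include_seed_irradiated Include the seed point in the irradiated
#'   arm's fit too? Default `FALSE` (radiation kills part of the seed, so
#'   the pre-irradiation count does not lie on the irradiated growth
#'   curve).
#' @param method Fit method, see [fit_exponential()].
#' @return A list of class `assay_report`: `ratios` tibble, `control_fit`,
#'   `irradiated_fit`, `SF2`, `division_time` tibble.
#' @examples
#' rep <- assay_analysis()
#' rep$SF2
#' @export
assay_analysis <- function(counts = assay_counts(),
                           seed_millions = attr(counts, "seed_millions"),
                           include_seed_irradiated = FALSE,
                           method = c("loglinear", "nls")) {
  method <- match.arg(method)
  ctrl <- counts[!counts$irradiated, ]
  irr <- counts[counts$irradiated, ]
  ctrl_fit <- fit_exponential(ctrl, seed_millions = seed_millions,
                              include_seed = !is.null(seed_millions),
                              method = method)
  irr_fit <- fit_exponential(irr, seed_millions = seed_millions,
                             include_seed = include_seed_irradiated,
                             method = method)
  structure(list(
    ratios = count_ratios(irr, ctrl),
    control_fit = ctrl_fit,
    irradiated_fit = irr_fit,
    SF2 = surviving_fraction(irr_fit, ctrl_fit),
    division_time = division_time(ctrl_fit$k)
  ), class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat("<assay_report>\n")
  cat("  count ratios (irradiated / control):\n")
  for (i in seq_len(nrow(x$ratios))) {
    cat(sprintf("    day %g: %.2f\n", x$ratios$day[i], x$ratios$ratio[i]))
  }
  cat(sprintf("  day-0 extrapolates: control %.4g M, irradiated %.4g M\n",
              x$control_fit$N0, x$irradiated_fit$N0))
  cat(sprintf("  SF2 = %.2f;  division time %.2f d (%.1f h)\n",
              x$SF2, x$division_time$days, x$division_time$hours))
  invisible(x)
}

#' Write an assay report as JSON
#'
#' @param report An `assay_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_assay_report <- function(report, path) {
  out <- list(
    ratios = report$ratios,
    control = list(N0 = report$control_fit$N0, k = report$control_fit$k),
    irradiated = list(N0 = report$irradiated_fit$N0,
                      k = report$irradiated_fit$k),
    SF2 = report$SF2,
    division_time_days = report$division_time$days,
    division_time_hours = report$division_time$hours
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
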