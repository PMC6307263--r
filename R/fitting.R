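# Least-squares estimation of (delta, p, SF_u, T_h) from a daily
# tumor-volume series, with SF_v tied to the histology's population
# surviving fraction through the mixing relation.  The objective is the
# square root of the mean *absolute* deviation between the normalized
# measured and modelled series (as defined for this model), which is
# non-smooth, so the search is derivative-free: a deterministic coarse
# grid followed by Nelder-Mead restarts on a logit-transformed box.

align_course_volumes <- function(course, volumes) {
  validate_course(course)
  if (is.null(volumes)) volumes <- volume_series(course)
  if (!is.data.frame(volumes) ||
      !all(c("date", "volume_cm3") %in% names(volumes))) {
    abort("`volumes` needs columns `date` and `volume_cm3`.",
          class = "csck_config_error")
  }
  if (nrow(volumes) == 0L) {
    abort("No volume measurements supplied.", class = "csck_config_error")
  }
  if (any(volumes$volume_cm3 <= 0) || volumes$volume_cm3[1L] <= 0) {
    abort("Measured volumes must be positive.", class = "csck_config_error")
  }
  idx <- match(as.Date(volumes$date), course$date)
  if (anyNA(idx)) {
    abort("Some measurement dates are not days of the course.",
          class = "csck_config_error")
  }
  list(
    flags = course$fraction,
    idx = idx,
    dates = as.Date(volumes$date),
    M = volumes$volume_cm3,
    M_norm = volumes$volume_cm3 / volumes$volume_cm3[1L]
  )
}

# Normalized model trajectory (G_i / G_0) over `flags`, computed with the
# two per-flag daily propagators.
trajectory_norm <- function(flags, Pt, Pu, p) {
  n <- length(flags)
  g <- numeric(n)
  s <- c(p, 1 - p, 0)
  g[1L] <- 1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      s <- drop((if (flags[i]) Pt else Pu) %*% s)
      g[i + 1L] <- s[1L] + s[2L] + s[3L]
    }
  }
  g
}

objective_value <- function(m_norm, g_norm, variant = "printed") {
  d <- abs(m_norm - g_norm)
  if (variant == "rms") sqrt(mean(d^2)) else sqrt(mean(d))
}

#' Goodness-of-fit objective between measured and modelled volumes
#'
#' The objective minimized by [fit_parameters()]: with measured volumes
#' `M_i` (normalized to the first measurement `M_0`) and modelled total
#' cell counts `G_i` (normalized to `G_0`),
#' `R = sqrt(mean(|M_i / M_0 - G_i / G_0|))` — the square root of the mean
#' absolute deviation, taken over the imaging days. A conventional
#' root-mean-square variant is available but is not the definition used
#' throughout (`variant = "rms"`).
#'
#' @param params A [kinetic_parameters()] object.
#' @param course A `treatment_course` tibble.
#' @param volumes Measured volumes: a tibble `(date, volume_cm3)`. Defaults
#'   to the measurements stored in `course`. Every measurement date must be
#'   a day of the course.
#' @param variant `"printed"` (mean absolute deviation under the root; the
#'   model's definition) or `"rms"`.
#' @param legacy Use legacy sign conventions? See [step_coefficients()].
#' @return The objective value `R >= 0`.
#' @export
objective_r <- function(params, course, volumes = NULL,
                        variant = c("printed", "rms"), legacy = FALSE) {
  variant <- match.arg(variant)
  validate_kinetic_parameters(params)
  al <- align_course_volumes(course, volumes)
  Pt <- day_propagator(params, treated = TRUE, legacy = legacy)
  Pu <- day_propagator(params, treated = FALSE, legacy = legacy)
  g <- trajectory_norm(al$flags, Pt, Pu, params$p)
  objective_value(al$M_norm, g[al$idx], variant)
}

#' Optimizer settings for parameter fitting
#'
#' @param n_starts Number of Nelder-Mead starts taken from the best points
#'   of the deterministic coarse grid.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param n_restarts Polishing restarts of the best solution (a fresh
#'   simplex at the incumbent; helps on non-smooth objectives).
#' @param grid Named list of candidate values per parameter
#'   (`delta`, `p`, `SF_u`, `T_h`) whose Cartesian product forms the coarse
#'   start grid.
#' @param bounds Named list of `c(lower, upper)` search bounds.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 8,
                        maxit = 2000,
                        reltol = 1e-12,
                        n_restarts = 8,
                        grid = list(
                          delta = c(0.005, 0.02, 0.05, 0.1, 0.18),
                          p     = c(0.05, 0.15, 0.25, 0.4, 0.55, 0.75),
                          SF_u  = c(0.90, 0.95, 0.975, 0.995),
                          T_h   = c(0.3, 0.8, 1.5, 3, 8, 15)
                        ),
                        bounds = list(
                          delta = c(0.001, 0.2),
                          p     = c(0.001, 0.999),
                          SF_u  = c(0.001, 1),
                          T_h   = c(0.1, 20)
                        )) {
  structure(list(n_starts = n_starts, maxit = maxit, reltol = reltol,
                 n_restarts = n_restarts, grid = grid, bounds = bounds),
            class = "fit_control")
}

to_unconstrained <- function(x, bounds) {
  qlogis((x - bounds[1L]) / (bounds[2L] - bounds[1L]))
}

from_unconstrained <- function(z, bounds) {
  bounds[1L] + (bounds[2L] - bounds[1L]) * plogis(z)
}

#' Estimate patient-specific radiobiological parameters
#'
#' Fits the free parameters `(delta, p, SF_u, T_h)` of the kinetic model to
#' a daily tumor-volume series by minimizing [objective_r()], with the
#' tumor-cell surviving fraction tied to the histology's population value
#' via `SF_v = (SF_T - p * SF_u) / (1 - p)` (see [solve_sf_v()]) and the
#' shared doubling time `T_u = T_v = T_a` fixed at `T_days` (the histology
#' potential doubling time unless overridden). Parameter combinations whose
#' implied `SF_v` leaves `(0, 1]` are rejected during the search.
#'
#' The search is deterministic: objective evaluation on a coarse grid of
#' feasible candidates, Nelder-Mead from the best `n_starts`, then
#' polishing restarts at the incumbent.
#'
#' @inheritParams objective_r
#' @param preset A [histology_preset()] (or its name).
#' @param T_days Shared doubling time in days; default `preset$T_pot`.
#' @param control A [fit_control()] list.
#' @return An object of class `rt_fit` with elements `estimate` (tibble of
#'   `term`, `estimate`), `R`, `percent_errors` (`mean`, `sd`, `per_day`),
#'   `trajectory` (per-day tibble with `measured_norm`, `modelled_norm`,
#'   `abs_diff`), `diagnostics` (per-start tibble), plus the inputs needed
#'   to reproduce the fit. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' spec <- synthetic_spec(patient = "S1", noise_sd = 0, seed = 1)
#' crs <- generate_volumes(spec)
#' fit <- fit_parameters(crs, preset = "squamous")
#' tidy(fit)
#' }
#' @export
fit_parameters <- function(course, volumes = NULL, preset,
                           T_days = NULL, control = fit_control(),
                           variant = c("printed", "rms"), legacy = FALSE) {
  variant <- match.arg(variant)
  if (is.character(preset)) preset <- histology_preset(preset)
  if (is.null(T_days)) T_days <- preset$T_pot
  al <- align_course_volumes(course, volumes)
  if (length(al$M) < 5L) {
    abort("At least 5 volume measurements are required.",
          class = "csck_config_error")
  }
  SF_T <- preset$SF_T
  bounds <- control$bounds

  eval_theta <- function(delta, p, SF_u, T_h) {
    sf_v <- (SF_T - p * SF_u) / (1 - p)
    if (!is.finite(sf_v) || sf_v <= 0 || sf_v > 1) {
      # continuous infeasibility penalty, well above any attainable R
      excess <- if (!is.finite(sf_v)) 1 else max(-sf_v, sf_v - 1, 0)
      return(2 + 10 * excess)
    }
    pars <- structure(list(delta = delta, p = p, T_u = T_days, T_v = T_days,
                           T_a = T_days, T_h = T_h, SF_u = SF_u,
                           SF_v = sf_v), class = "kinetic_parameters")
    Pt <- day_propagator(pars, treated = TRUE, legacy = legacy)
    Pu <- day_propagator(pars, treated = FALSE, legacy = legacy)
    g <- trajectory_norm(al$flags, Pt, Pu, p)
    objective_value(al$M_norm, g[al$idx], variant)
  }

  cand <- expand.grid(delta = control$grid$delta, p = control$grid$p,
                      SF_u = control$grid$SF_u, T_h = control$grid$T_h,
                      KEEP.OUT.ATTRS = FALSE)
  cand$sf_v <- (SF_T - cand$p * cand$SF_u) / (1 - cand$p)
  cand <- cand[cand$sf_v > 0 & cand$sf_v <= 1, , drop = FALSE]
  if (nrow(cand) == 0L) {
    abort("No feasible start point under the preset SF_T.",
          class = "csck_infeasible_error")
  }
  cand$value <- vapply(seq_len(nrow(cand)), function(i) {
    eval_theta(cand$delta[i], cand$p[i], cand$SF_u[i], cand$T_h[i])
  }, numeric(1L))
  cand <- cand[order(cand$value), , drop = FALSE]
  starts <- utils::head(cand, control$n_starts)

  fn <- function(z) {
    eval_theta(from_unconstrained(z[1L], bounds$delta),
               from_unconstrained(z[2L], bounds$p),
               from_unconstrained(z[3L], bounds$SF_u),
               from_unconstrained(z[4L], bounds$T_h))
  }
  run_nm <- function(z0) {
    optim(z0, fn, method = "Nelder-Mead",
          control = list(maxit = control$maxit, reltol = control$reltol))
  }

  diag_rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    z0 <- c(to_unconstrained(starts$delta[i], bounds$delta),
            to_unconstrained(starts$p[i], bounds$p),
            to_unconstrained(starts$SF_u[i], bounds$SF_u),
            to_unconstrained(starts$T_h[i], bounds$T_h))
    res <- run_nm(z0)
    diag_rows[[i]] <- tibble::tibble(
      start = i,
      start_delta = starts$delta[i], start_p = starts$p[i],
      start_SF_u = starts$SF_u[i], start_T_h = starts$T_h[i],
      value = res$value, convergence = res$convergence
    )
    if (is.null(best) || res$value < best$value) best <- res
  }
  for (k in seq_len(control$n_restarts)) {
    res <- run_nm(best$par)
    improvement <- best$value - res$value
    if (res$value < best$value) best <- res
    if (improvement < 1e-14) break
  }
  if (all(vapply(diag_rows, function(d) d$convergence != 0, logical(1L))) &&
      best$convergence != 0) {
    abort("Optimizer failed to converge from every start.",
          class = "csck_optimizer_error")
  }

  delta <- from_unconstrained(best$par[1L], bounds$delta)
  p     <- from_unconstrained(best$par[2L], bounds$p)
  SF_u  <- from_unconstrained(best$par[3L], bounds$SF_u)
  T_h   <- from_unconstrained(best$par[4L], bounds$T_h)
  SF_v  <- solve_sf_v(SF_T, p, SF_u)
  params <- kinetic_parameters(delta = delta, p = p, T_u = T_days,
                               T_h = T_h, SF_u = SF_u, SF_v = SF_v)

  sim <- simulate_course(params, course, legacy = legacy)
  measured_norm <- rep(NA_real_, nrow(course))
  measured_norm[al$idx] <- al$M_norm
  trajectory <- tibble::tibble(
    date = course$date, day = course$day, fraction = course$fraction,
    measured_norm = measured_norm, modelled_norm = sim$total_norm,
    abs_diff = abs(measured_norm - sim$total_norm)
  )
  per_day <- tibble::tibble(
    date = al$dates, day = course$day[al$idx],
    measured_norm = al$M_norm, modelled_norm = sim$total_norm[al$idx],
    pct_error = 100 * abs(al$M_norm - sim$total_norm[al$idx])
  )

  structure(list(
    estimate = tibble::tibble(
      term = c("delta", "p", "SF_u", "SF_v", "T_h"),
      estimate = c(delta, p, SF_u, SF_v, T_h)
    ),
    params = params,
    R = best$value,
    percent_errors = list(mean = mean(per_day$pct_error),
                          sd = sd(per_day$pct_error),
                          per_day = per_day),
    trajectory = trajectory,
    diagnostics = list(starts = dplyr::bind_rows(diag_rows),
                       convergence = best$convergence,
                       n_measurements = length(al$M),
                       seed = NA_integer_),  # the search is deterministic
    preset = preset, T_days = T_days, variant = variant, legacy = legacy,
    course = course, volumes = tibble::tibble(date = al$dates,
                                              volume_cm3 = al$M),
    control = control
  ), class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat("<rt_fit>  kinetic-model fit to", x$diagnostics$n_measurements,
      "volume measurements\n")
  cat(sprintf("  preset: %s (SF_T = %.2f), shared doubling time %.3g d\n",
              x$preset$name, x$preset$SF_T, x$T_days))
  est <- setNames(x$estimate$estimate, x$estimate$term)
  cat(sprintf("  delta = %.3f  p = %.3f  SF_u = %.3f  SF_v = %.3f  T_h = %.2f d\n",
              est["delta"], est["p"], est["SF_u"], est["SF_v"], est["T_h"]))
  cat(sprintf("  R = %.4g   fit error %% = %.2f +/- %.2f\n",
              x$R, x$percent_errors$mean, x$percent_errors$sd))
  invisible(x)
}

#' Tidy a kinetic-model fit
#'
#' @param x An `rt_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`).
#' @method tidy rt_fit
#' @export
tidy.rt_fit <- function(x, ...) x$estimate

#' One-row summary of a kinetic-model fit
#'
#' @param x An `rt_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: objective `R`, percent-error mean and SD,
#'   number of measurements, convergence flag.
#' @method glance rt_fit
#' @export
glance.rt_fit <- function(x, ...) {
  tibble::tibble(
    R = x$R,
    pct_error_mean = x$percent_errors$mean,
    pct_error_sd = x$percent_errors$sd,
    n = x$diagnostics$n_measurements,
    convergence = x$diagnostics$convergence
  )
}

#' Percent-error statistics between modelled and measured series
#'
#' Per imaging day the error is `100 * |M_i / M_0 - G_i / G_0|`; the
#' summary is the sample mean and the `n - 1` sample standard deviation.
#'
#' @param modelled_norm,measured_norm Aligned normalized series (equal
#'   length).
#' @return A one-row tibble `(mean_pct, sd_pct, n)`.
#' @export
percent_error_stats <- function(modelled_norm, measured_norm) {
  if (length(modelled_norm) != length(measured_norm)) {
    abort("Series lengths differ.", class = "csck_config_error")
  }
  err <- 100 * abs(measured_norm - modelled_norm)
  tibble::tibble(mean_pct = mean(err), sd_pct = sd(err), n = length(err))
}

#' Compare candidate doubling times by fit quality
#'
#' Refits the model three times with the shared doubling time
#' `T_u = T_v = T_a` set to the histology's potential doubling time
#' (`T_pot`), in-vitro cell division time (`T_div`) and clinical volume
#' doubling time (`T_vol`), and reports the optimized objective for each.
#' Short division times make the modelled trajectory regrow sharply over
#' untreated weekends (a zigzag), very long volume doubling times make it
#' too smooth; the potential doubling time typically fits best.
#'
#' @inheritParams fit_parameters
#' @return A tibble with columns `doubling_time` (`"T_pot"`, `"T_div"`,
#'   `"T_vol"`), `T_days`, `R`, and a list-column `fit` of the underlying
#'   `rt_fit` objects.
#' @export
doubling_time_comparison <- function(course, volumes = NULL, preset,
                                     control = fit_control(),
                                     legacy = FALSE) {
  if (is.character(preset)) preset <- histology_preset(preset)
  cands <- c(T_pot = preset$T_pot, T_div = preset$T_div, T_vol = preset$T_vol)
  fits <- purrr::map(cands, function(Td) {
    fit_parameters(course, volumes, preset, T_days = Td,
                   control = control, legacy = legacy)
  })
  tibble::tibble(
    doubling_time = names(cands),
    T_days = unname(cands),
    R = purrr::map_dbl(fits, "R"),
    fit = unname(fits)
  )
}

#' One-parameter stability scan of the objective
#'
#' Slices the objective `R` along one parameter with all others held at the
#' fitted values — a pure one-dimensional slice: when `p` or `SF_u` is
#' scanned, `SF_v` is *not* re-tied to the population surviving fraction.
#' A well-identified parameter shows a single clear minimum at the
#' estimate.
#'
#' @param fit An `rt_fit` object.
#' @param parameter One of `"p"`, `"delta"`, `"SF_u"`, `"SF_v"`.
#' @param grid Grid of values; defaults to 100 evenly spaced points over
#'   the documented scan range (`p`, `SF_u`, `SF_v` in `[0.001, 1]`,
#'   `delta` in `[0.001, 0.2]`).
#' @return A tibble `(parameter, value, R)` of class `stability_scan`.
#' @export
stability_scan <- function(fit, parameter = c("p", "delta", "SF_u", "SF_v"),
                           grid = NULL) {
  parameter <- match.arg(parameter)
  if (!inherits(fit, "rt_fit")) {
    abort("`fit` must be an rt_fit object.", class = "csck_config_error")
  }
  ranges <- list(p = c(0.001, 1), delta = c(0.001, 0.2),
                 SF_u = c(0.001, 1), SF_v = c(0.001, 1))
  if (is.null(grid)) {
    grid <- seq(ranges[[parameter]][1L], ranges[[parameter]][2L],
                length.out = 100L)
  }
  base <- fit$params
  al <- align_course_volumes(fit$course, fit$volumes)
  Rs <- vapply(grid, function(val) {
    pars <- base
    pars[[if (parameter == "delta") "delta" else parameter]] <- val
    Pt <- day_propagator(pars, treated = TRUE, legacy = fit$legacy)
    Pu <- day_propagator(pars, treated = FALSE, legacy = fit$legacy)
    g <- trajectory_norm(al$flags, Pt, Pu, pars$p)
    objective_value(al$M_norm, g[al$idx], fit$variant)
  }, numeric(1L))
  structure(tibble::tibble(parameter = parameter, value = grid, R = Rs),
            class = c("stability_scan", class(tibble::tibble())))
}

#' Write a fit report to disk
#'
#' Writes the fitted parameters, objective value, percent-error statistics
#' and optimizer diagnostics as JSON, and optionally the per-day trajectory
#' (`date, measured_norm, modelled_norm, abs_diff`) as CSV.
#'
#' @param fit An `rt_fit` object.
#' @param json_path Output path for the JSON report.
#' @param csv_path Optional output path for the trajectory CSV.
#' @return Invisibly, `json_path`.
#' @export
write_fit_report <- function(fit, json_path, csv_path = NULL) {
  est <- setNames(as.list(fit$estimate$estimate), fit$estimate$term)
  report <- list(
    preset = fit$preset$name,
    SF_T = fit$preset$SF_T,
    T_days = fit$T_days,
    estimate = est,
    R = fit$R,
    percent_errors = list(mean = fit$percent_errors$mean,
                          sd = fit$percent_errors$sd),
    diagnostics = list(
      convergence = fit$diagnostics$convergence,
      n_measurements = fit$diagnostics$n_measurements,
      starts = fit$diagnostics$starts
    ),
    package_version = as.character(packageVersion("csckinetics"))
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    tr <- fit$trajectory[, c("date", "measured_norm", "modelled_norm",
                             "abs_diff")]
    write.csv(tr, csv_path, row.names = FALSE, na = "")
  }
  invisible(json_path)
}
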