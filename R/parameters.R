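#' Kinetic model parameters
#'
#' Constructs and validates the parameter set of the three-compartment
#' (cancer stem-like cell / non-stem tumor cell / dead cell) kinetic model of
#' tumor response to fractionated radiotherapy.
#'
#' The model follows cell counts per unit initial volume in three
#' compartments: `U` (CSCs, self-renewing, radio-resistant), `V` (non-stem
#' tumor cells, produced by asymmetric CSC division) and `W` (dead cells,
#' still occupying imaged volume until cleared). Division, death and
#' clearance are first-order processes with rates derived from doubling /
#' half times; radiation enters as a per-fraction surviving fraction applied
#' continuously over each treated day.
#'
#' @param delta Probability that a CSC division is symmetric (two CSCs), in
#'   `[0, 1]`. Equivalently the CSC self-renewal rate per division.
#' @param p Initial proportion of CSCs, `U0 / (U0 + V0)`, in `[0, 1]`.
#' @param T_u CSC doubling time, days (> 0).
#' @param T_v Tumor-cell doubling time, days (> 0). Defaults to `T_u`: the
#'   fitting procedure assumes CSCs and TCs share one doubling time.
#' @param T_a Half-time of programmed (radiation-independent) tumor-cell
#'   death, days (> 0). Defaults to `T_u` for the same reason.
#' @param T_h Half-time of dead-cell clearance from the imaged volume, days.
#' @param SF_u CSC surviving fraction per 2 Gy fraction, in `(0, 1]`.
#' @param SF_v Tumor-cell surviving fraction per 2 Gy fraction, in `(0, 1]`.
#'
#' @return An object of class `kinetic_parameters` (a named list).
#' @examples
#' kinetic_parameters(delta = 0.018, p = 0.416, T_u = 7.1, T_h = 1.5,
#'                    SF_u = 0.950, SF_v = 0.385)
#' @export
kinetic_parameters <- function(delta, p, T_u, T_v = T_u, T_a = T_u, T_h,
                               SF_u, SF_v) {
  params <- list(delta = delta, p = p, T_u = T_u, T_v = T_v, T_a = T_a,
                 T_h = T_h, SF_u = SF_u, SF_v = SF_v)
  validate_kinetic_parameters(params)
  structure(params, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(params) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "csck_invalid_parameter")
    }
  }
  for (nm in names(params)) num1(params[[nm]], nm)
  for (nm in c("T_u", "T_v", "T_a", "T_h")) {
    if (params[[nm]] <= 0) {
      abort(sprintf("`%s` must be strictly positive (days).", nm),
            class = "csck_invalid_parameter")
    }
  }
  for (nm in c("delta", "p")) {
    if (params[[nm]] < 0 || params[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", nm),
            class = "csck_invalid_parameter")
    }
  }
  for (nm in c("SF_u", "SF_v")) {
    if (params[[nm]] <= 0 || params[[nm]] > 1) {
      abort(sprintf("`%s` must lie in (0, 1].", nm),
            class = "csck_invalid_parameter")
    }
  }
  invisible(params)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>\n")
  cat(sprintf("  delta = %.4g  p = %.4g\n", x$delta, x$p))
  cat(sprintf("  T_u = %.4g d  T_v = %.4g d  T_a = %.4g d  T_h = %.4g d\n",
              x$T_u, x$T_v, x$T_a, x$T_h))
  cat(sprintf("  SF_u = %.4g  SF_v = %.4g  (per 2 Gy fraction)\n",
              x$SF_u, x$SF_v))
  invisible(x)
}

#' Derive per-day rates from kinetic parameters
#'
#' Converts doubling / half times to first-order rates and the surviving
#' fractions to radiation kill rates. On an untreated day the kill rates
#' `gamma_u`, `gamma_v` are zero (surviving fraction 1); all other rates are
#' unaffected by treatment status.
#'
#' @param params A [kinetic_parameters()] object.
#' @param treated Logical: is a 2 Gy fraction delivered on this day?
#'
#' @return A named list with components `m_u`, `m_v`, `m_a` (division /
#'   programmed-death rates, per day), `gamma_u`, `gamma_v` (radiation kill
#'   rates, per day) and `gamma_w` (dead-cell clearance rate, per day).
#' @examples
#' p <- kinetic_parameters(0.02, 0.3, T_u = 6.2, T_h = 1, SF_u = 0.98,
#'                         SF_v = 0.874)
#' derive_rates(p, treated = TRUE)$gamma_u   # -log(0.98)
#' @export
derive_rates <- function(params, treated = TRUE) {
  validate_kinetic_parameters(params)
  list(
    m_u     = log(2) / params$T_u,
    m_v     = log(2) / params$T_v,
    m_a     = log(2) / params$T_a,
    gamma_u = if (treated) -log(params$SF_u) else 0,
    gamma_v = if (treated) -log(params$SF_v) else 0,
    gamma_w = log(2) / params$T_h
  )
}

#' Exponential step coefficients of the analytic solution
#'
#' The closed-form solution of the compartment ODEs is a sum of
#' exponentials with rates `A` (net CSC rate), `C` (net TC rate) and
#' `-gamma_w` (clearance); `B` is the asymmetric-division inflow rate from
#' CSCs into the TC compartment.
#'
#' `A = delta * m_u - gamma_u` and `B = (1 - delta) * m_u`. For `C` two
#' conventions exist: the ODE-consistent form `C = m_v - m_a - gamma_v`
#' (default; programmed death drains the TC compartment) and a legacy form
#' `C = m_v + m_a - gamma_v` found in some write-ups of the solution. Under
#' the fitting assumption `T_a = T_v` the untreated-day values differ
#' (`0` vs `2 m_v`), so the distinction matters; the ODE-consistent form is
#' the one validated by the Euler integrator. See [advance_one_day()].
#'
#' @param rates Output of [derive_rates()].
#' @param delta Symmetric-division probability in `[0, 1]`.
#' @param legacy_c Use the legacy sign convention for `C`? Default `FALSE`.
#'
#' @return A named list with components `A`, `B`, `C` (per day).
#' @export
step_coefficients <- function(rates, delta, legacy_c = FALSE) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0, delta <= 1)
  list(
    A = delta * rates$m_u - rates$gamma_u,
    B = (1 - delta) * rates$m_u,
    C = if (legacy_c) rates$m_v + rates$m_a - rates$gamma_v
        else          rates$m_v - rates$m_a - rates$gamma_v
  )
}

#' Population surviving fraction from the compartment mixture
#'
#' The surviving fraction of the whole cell population after one 2 Gy
#' fraction is the CSC-proportion-weighted convex combination
#' `SF_T = p * SF_u + (1 - p) * SF_v`.
#'
#' @param p CSC proportion in `[0, 1]`.
#' @param SF_u,SF_v Surviving fractions of CSCs and TCs in `[0, 1]`.
#' @return The total surviving fraction, a scalar in
#'   `[min(SF_u, SF_v), max(SF_u, SF_v)]`.
#' @examples
#' sf_total(0.416, 0.950, 0.385)  # ~0.62, adenocarcinoma
#' @export
sf_total <- function(p, SF_u, SF_v) {
  for (x in list(p = p, SF_u = SF_u, SF_v = SF_v)) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      abort("`p`, `SF_u` and `SF_v` must lie in [0, 1].",
            class = "csck_domain_error")
    }
  }
  p * SF_u + (1 - p) * SF_v
}

#' Tumor-cell surviving fraction implied by a fixed population mixture
#'
#' During fitting the population surviving fraction `SF_T` is fixed at its
#' histology-specific literature value and `p`, `SF_u` are free, so
#' `SF_v = (SF_T - p * SF_u) / (1 - p)` is implied. Combinations for which
#' the implied value falls outside `(0, 1]` are infeasible.
#'
#' @param SF_T Population surviving fraction in `(0, 1]`.
#' @param p CSC proportion in `[0, 1)`.
#' @param SF_u CSC surviving fraction in `(0, 1]`.
#' @return The implied `SF_v`, a scalar in `(0, 1]`.
#' @examples
#' solve_sf_v(0.62, 0.416, 0.950)  # ~0.385
#' @export
solve_sf_v <- function(SF_T, p, SF_u) {
  if (!is.finite(p) || p < 0 || p >= 1) {
    abort("`p` must lie in [0, 1); p = 1 leaves SF_v undetermined.",
          class = "csck_degenerate_error")
  }
  if (SF_T <= 0 || SF_T > 1 || SF_u <= 0 || SF_u > 1) {
    abort("`SF_T` and `SF_u` must lie in (0, 1].", class = "csck_domain_error")
  }
  sf_v <- (SF_T - p * SF_u) / (1 - p)
  if (!is.finite(sf_v) || sf_v <= 0 || sf_v > 1) {
    abort(sprintf(
      "Implied SF_v = %.4g is outside (0, 1]: (p, SF_u) infeasible for SF_T = %.3g.",
      sf_v, SF_T), class = "csck_infeasible_error")
  }
  sf_v
}

#' Histology presets for the kinetic model
#'
#' Literature constants used to pin the population surviving fraction and
#' the shared doubling time for the two lung-cancer histologies studied:
#' squamous cell carcinoma (`SF_T` = 0.90 at 2 Gy, potential doubling time
#' `T_pot` = 6.2 d, in-vitro division time `T_div` = 60 h, volume doubling
#' time `T_vol` = 115.2 d) and adenocarcinoma (`SF_T` = 0.62, `T_pot` =
#' 7.1 d, `T_div` = 22 h, `T_vol` = 221.6 d). The all-histology average
#' volume doubling time (166.3 d) is retained as metadata.
#'
#' @param name `"squamous"`, `"adenocarcinoma"`, or `"custom"` (supply the
#'   remaining arguments).
#' @param SF_T,T_pot,T_div_hours,T_vol Custom constants; ignored unless
#'   `name = "custom"`.
#' @return An object of class `histology_preset`: a list with fields `name`,
#'   `SF_T`, `T_pot` (d), `T_div` (d), `T_div_hours`, `T_vol` (d) and
#'   `T_vol_overall` (d).
#' @examples
#' histology_preset("squamous")$SF_T   # 0.90
#' @export
histology_preset <- function(name = c("squamous", "adenocarcinoma", "custom"),
                             SF_T = NULL, T_pot = NULL, T_div_hours = NULL,
                             T_vol = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    squamous = list(name = "squamous", SF_T = 0.90, T_pot = 6.2,
                    T_div_hours = 60, T_vol = 115.2),
    adenocarcinoma = list(name = "adenocarcinoma", SF_T = 0.62, T_pot = 7.1,
                          T_div_hours = 22, T_vol = 221.6),
    custom = list(name = "custom", SF_T = SF_T, T_pot = T_pot,
                  T_div_hours = T_div_hours, T_vol = T_vol)
  )
  if (any(vapply(preset, is.null, logical(1L)))) {
    abort("Custom presets need `SF_T`, `T_pot`, `T_div_hours` and `T_vol`.",
          class = "csck_invalid_parameter")
  }
  stopifnot(preset$SF_T > 0, preset$SF_T < 1, preset$T_pot > 0,
            preset$T_div_hours > 0, preset$T_vol > 0)
  preset$T_div <- preset$T_div_hours / 24
  preset$T_vol_overall <- 166.3
  structure(preset, class = "histology_preset")
}

#' @export
print.histology_preset <- function(x, ...) {
  cat(sprintf("<histology_preset: %s>\n", x$name))
  cat(sprintf("  SF_T = %.2f   T_pot = %.1f d   T_div = %.2f d (%g h)   T_vol = %.1f d\n",
              x$SF_T, x$T_pot, x$T_div, x$T_div_hours, x$T_vol))
  invisible(x)
}
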