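# Closed-form solution of the compartment ODE system
#
#   u' = (delta*m_u - gamma_u) u                       = A u
#   v' = (1-delta)*m_u u + (m_v - m_a - gamma_v) v     = B u + C v
#   w' = gamma_u u + (m_a + gamma_v) v - gamma_w w
#
# The system is linear with constant coefficients within a day, so the
# daily update is a lower-triangular 3x3 propagator matrix.  All
# exponential-difference quotients are evaluated through expm1() (or a
# series near-degenerate) so that resonant denominators (A ~ C,
# A ~ -gamma_w, C ~ -gamma_w) never blow up; below DEGEN_TOL the exact
# analytic limit (t e^{At}-type terms) is used.

DEGEN_TOL <- 1e-9

# (e^{a t} - e^{b t}) / (a - b); cancellation-free via expm1, exact limit
# t e^{a t} as a -> b.
exp_diff_quot <- function(a, b, t) {
  d <- (a - b) * t
  if (abs(d) < .Machine$double.xmin) return(t * exp(a * t))
  exp(b * t) * t * (expm1(d) / d)
}

# int_0^t s e^{a s + b (t - s)} ds  ==  d/da of exp_diff_quot(a, b, t)
time_weighted_quot <- function(a, b, t) {
  x <- (a - b) * t
  if (abs(x) < 1e-2) {
    # series of (x e^x - expm1(x)) / x^2 about 0
    g <- 1 / 2 + x / 3 + x^2 / 8 + x^3 / 30 + x^4 / 144 + x^5 / 840
    return(exp(b * t) * t^2 * g)
  }
  exp(b * t) * t^2 * (x * exp(x) - expm1(x)) / x^2
}

# ( exp_diff_quot(a, c_) - exp_diff_quot(c_, c_w...) ) / (a - c_) handled
# robustly: the W-row needs (Phi(A,-gw) - Phi(C,-gw)) / (A - C), whose
# limit as A -> C is the time-weighted quotient.
phi_slope <- function(a, c_, b, t) {
  d <- a - c_
  if (abs(d) < DEGEN_TOL) return(time_weighted_quot(a, b, t))
  if (abs(d * t) < 1e-4) return(time_weighted_quot((a + c_) / 2, b, t))
  (exp_diff_quot(a, b, t) - exp_diff_quot(c_, b, t)) / d
}

# 3x3 propagator over t days at constant treatment status.  State order
# (U, V, W); next = P %*% state.
day_propagator <- function(params, treated = TRUE, t = 1, legacy = FALSE) {
  r <- derive_rates(params, treated = treated)
  co <- step_coefficients(r, params$delta, legacy_c = legacy)
  A <- co$A; B <- co$B; C <- co$C
  gw <- r$gamma_w
  q <- if (legacy) r$m_v + r$gamma_v else r$m_a + r$gamma_v  # V -> W inflow
  eA <- exp(A * t); eC <- exp(C * t); eW <- exp(-gw * t)
  phiAC <- exp_diff_quot_lim(A, C, t)
  phiAW <- exp_diff_quot(A, -gw, t)
  phiCW <- exp_diff_quot(C, -gw, t)
  P <- matrix(0, 3L, 3L)
  P[1L, 1L] <- eA
  P[2L, 1L] <- B * phiAC
  P[2L, 2L] <- eC
  P[3L, 1L] <- r$gamma_u * phiAW + q * B * phi_slope(A, C, -gw, t)
  P[3L, 2L] <- q * phiCW
  P[3L, 3L] <- eW
  P
}

# As exp_diff_quot but with the documented degenerate-tolerance switch,
# used where the quotient multiplies B (the v-row resonance A ~ C).
exp_diff_quot_lim <- function(a, b, t) {
  if (abs(a - b) < DEGEN_TOL) return(t * exp(a * t))
  exp_diff_quot(a, b, t)
}

#' Compartment state
#'
#' A state of the kinetic model: cell counts (arbitrary units, conventionally
#' per unit initial volume) in the CSC (`U`), tumor-cell (`V`) and dead-cell
#' (`W`) compartments.
#'
#' @param U,V,W Non-negative cell counts.
#' @return A named numeric vector `c(U =, V =, W =)`.
#' @examples
#' compartment_state(0.3, 0.7, 0)
#' @export
compartment_state <- function(U, V, W = 0) {
  s <- c(U = as.numeric(U), V = as.numeric(V), W = as.numeric(W))
  validate_state(s)
  s
}

validate_state <- function(state) {
  if (length(state) != 3L || any(!is.finite(state))) {
    abort("A compartment state is three finite numbers (U, V, W).",
          class = "csck_invalid_state")
  }
  if (any(state < 0)) {
    abort("Compartment counts must be non-negative.",
          class = "csck_invalid_state")
  }
  invisible(state)
}

#' Total cell count of a state
#'
#' The quantity compared with (normalized) imaged tumor volume:
#' `G = U + V + W`, i.e. dead cells still count until cleared.
#'
#' @param state A [compartment_state()].
#' @return A scalar, `U + V + W`.
#' @export
total_cells <- function(state) {
  validate_state(state)
  sum(state)
}

#' Continuous-time analytic solution at constant treatment status
#'
#' Evaluates the closed-form solution of the compartment ODEs at time `t`
#' (days), assuming the treatment status is constant over `[0, t]`.
#' `analytic_state(s, p, treated, t = 1)` is exactly the one-day update
#' used by [advance_one_day()].
#'
#' @param state0 Initial [compartment_state()].
#' @param params A [kinetic_parameters()] object.
#' @param treated Logical: radiation delivered (continuously in effect)
#'   over the interval?
#' @param t Time in days, `>= 0`.
#' @param legacy Use the legacy `C` / dead-cell-inflow convention? See
#'   [step_coefficients()].
#' @return The state at time `t`.
#' @examples
#' s0 <- compartment_state(0.3, 0.7, 0)
#' pars <- kinetic_parameters(0.02, 0.3, T_u = 6.2, T_h = 1,
#'                            SF_u = 0.98, SF_v = 0.874)
#' analytic_state(s0, pars, treated = TRUE, t = 1)
#' @export
analytic_state <- function(state0, params, treated = TRUE, t = 1,
                           legacy = FALSE) {
  validate_state(state0)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    abort("`t` must be a single non-negative number of days.",
          class = "csck_domain_error")
  }
  if (t == 0) return(state0)
  P <- day_propagator(params, treated = treated, t = t, legacy = legacy)
  out <- drop(P %*% state0)
  # clip floating-point dust; the exact solution is non-negative
  names(out) <- c("U", "V", "W")
  pmax(out, 0)
}

#' One-day analytic update of the compartment state
#'
#' Advances the state across one calendar day using the closed-form
#' solution with `t = 1` day. On a treated day division, radiation kill
#' and dead-cell clearance act simultaneously as one linear system (the
#' per-fraction surviving fraction enters as a continuous kill rate
#' `-log(SF)` over the day); on an untreated day the kill rates are zero.
#'
#' @inheritParams analytic_state
#' @param state A [compartment_state()].
#' @return The next-day state.
#' @examples
#' pars <- kinetic_parameters(0.02, 0.3, T_u = 6.2, T_h = 1,
#'                            SF_u = 0.98, SF_v = 0.874)
#' advance_one_day(compartment_state(0.3, 0.7, 0), pars, treated = TRUE)
#' @export
advance_one_day <- function(state, params, treated = TRUE, legacy = FALSE) {
  analytic_state(state, params, treated = treated, t = 1, legacy = legacy)
}
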