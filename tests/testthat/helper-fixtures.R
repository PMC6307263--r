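# Shared fixtures: small parameter sets, courses, and a random-parameter
# generator used by the property-style suites.

squamous_params <- function(delta = 0.024, p = 0.242, T_days = 6.2,
                            T_h = 1.1, SF_u = 0.980, SF_v = 0.874) {
  kinetic_parameters(delta = delta, p = p, T_u = T_days, T_h = T_h,
                     SF_u = SF_u, SF_v = SF_v)
}

# a Monday; 33 weekday fractions span 45 calendar days
monday_course <- function(n_fractions = 33) {
  standard_course(as.Date("2017-01-02"), n_fractions = n_fractions)
}

# valid random parameter sets, away from the degenerate corners
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kinetic_parameters(
      delta = runif(1, 0, 0.3),
      p = runif(1, 0.05, 0.95),
      T_u = runif(1, 1, 20),
      T_v = runif(1, 1, 20),
      T_a = runif(1, 1, 20),
      T_h = runif(1, 0.3, 15),
      SF_u = runif(1, 0.5, 1),
      SF_v = runif(1, 0.3, 1)
    )
  })
}

recovery_truth <- function() {
  kinetic_parameters(delta = 0.03, p = 0.25, T_u = 6.2, T_h = 1.0,
                     SF_u = 0.98, SF_v = solve_sf_v(0.90, 0.25, 0.98))
}
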