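test_that("total_cells sums the compartments", {
  expect_identical(total_cells(compartment_state(0, 0, 0)), 0)
  expect_identical(total_cells(compartment_state(0.3, 0.7, 0)), 1)
  expect_identical(total_cells(compartment_state(1, 2, 3)), 6)
  expect_error(total_cells(c(-1, 0, 0)), class = "csck_invalid_state")
})

test_that("pure dead-cell clearance halves W at T_h = 1", {
  pars <- kinetic_parameters(0.1, 0.5, T_u = 5, T_h = 1,
                             SF_u = 0.9, SF_v = 0.9)
  nxt <- advance_one_day(compartment_state(0, 0, 4), pars, treated = TRUE)
  expect_equal(unname(nxt), c(0, 0, 2), tolerance = 1e-12)
})

test_that("pure symmetric division doubles U over one doubling time", {
  pars <- kinetic_parameters(1, 1, T_u = 5, T_h = 1, SF_u = 1, SF_v = 1)
  s <- compartment_state(1, 0, 0)
  for (i in 1:5) s <- advance_one_day(s, pars, treated = FALSE)
  expect_equal(s[["U"]], 2, tolerance = 1e-9)
})

test_that("a treated day with negligible division moves U loss into W", {
  # m_u ~ 0: U after a 2 Gy day is ~SF_u, killed cells appear in W
  pars <- kinetic_parameters(0.5, 1, T_u = 1e8, T_h = 1e8,
                             SF_u = 0.5, SF_v = 0.9)
  nxt <- advance_one_day(compartment_state(1, 0, 0), pars, treated = TRUE)
  expect_equal(nxt[["U"]], 0.5, tolerance = 1e-6)
  expect_equal(nxt[["W"]], 0.5, tolerance = 1e-6)
  expect_equal(sum(nxt), 1, tolerance = 1e-6)  # no clearance yet
})

test_that("analytic_state is the identity at t = 0 and constant when A = 0", {
  pars <- kinetic_parameters(0, 0.4, T_u = 6, T_h = 2, SF_u = 0.9,
                             SF_v = 0.8)
  s0 <- compartment_state(0.4, 0.3, 0.1)
  expect_identical(analytic_state(s0, pars, TRUE, t = 0), s0)
  # delta = 0 untreated: A = 0, U constant at any t
  u <- analytic_state(compartment_state(0.7, 0, 0), pars, FALSE, t = 3.7)
  expect_equal(u[["U"]], 0.7, tolerance = 1e-12)
  expect_error(analytic_state(s0, pars, TRUE, t = -1),
               class = "csck_domain_error")
})

test_that("the analytic flow has the semigroup property", {
  for (pars in random_params(20, seed = 7)) {
    s0 <- compartment_state(0.5, 0.4, 0.1)
    one <- advance_one_day(advance_one_day(s0, pars, TRUE), pars, TRUE)
    two <- analytic_state(s0, pars, TRUE, t = 2)
    expect_equal(unname(two), unname(one), tolerance = 1e-12)
  }
})

test_that("iterated daily updates equal the analytic solution at t = k", {
  k <- 7
  for (pars in random_params(10, seed = 11)) {
    s <- s0 <- compartment_state(0.3, 0.6, 0.1)
    for (i in seq_len(k)) s <- advance_one_day(s, pars, FALSE)
    direct <- analytic_state(s0, pars, FALSE, t = k)
    expect_equal(unname(s), unname(direct), tolerance = 1e-10)
  }
})

test_that("mass is conserved over a treated day when nothing grows or clears", {
  # all division/death/clearance off: radiation only shuffles U,V into W
  pars <- kinetic_parameters(0.3, 0.5, T_u = 1e12, T_v = 1e12,
                             T_a = 1e12, T_h = 1e12, SF_u = 0.7, SF_v = 0.4)
  s0 <- compartment_state(0.5, 0.5, 0)
  s1 <- advance_one_day(s0, pars, treated = TRUE)
  expect_equal(sum(s1), sum(s0), tolerance = 1e-10)
  expect_lt(s1[["U"]], s0[["U"]])
  expect_gt(s1[["W"]], 0)
})

test_that("one-day update matches the Euler oracle on random parameters", {
  worst <- 0
  for (pars in random_params(100, seed = 1)) {
    s0 <- compartment_state(pars$p, 1 - pars$p, 0)
    ana <- advance_one_day(s0, pars, treated = TRUE)
    num <- euler_integrate(s0, pars, TRUE, substeps = 1e4)
    num1 <- c(num$U[2], num$V[2], num$W[2])
    rel <- abs(num1 - ana) / ifelse(ana == 0, 1, ana)
    worst <- max(worst, rel)
    expect_lt(max(rel), 1e-3)
  }
  expect_lt(worst, 1e-3)
})

test_that("daily CSC survival e^A increases with delta and with SF_u", {
  base <- list(delta = 0.05, p = 0.3, T_days = 6.2, T_h = 1,
               SF_u = 0.9, SF_v = 0.874)
  surv_u <- function(delta, SF_u) {
    pars <- kinetic_parameters(delta, base$p, T_u = base$T_days,
                               T_h = base$T_h, SF_u = SF_u,
                               SF_v = base$SF_v)
    advance_one_day(compartment_state(1, 0, 0), pars, TRUE)[["U"]]
  }
  deltas <- seq(0, 1, by = 0.2)
  expect_true(all(diff(sapply(deltas, surv_u, SF_u = 0.9)) > 0))
  sfs <- seq(0.5, 1, by = 0.1)
  expect_true(all(diff(sapply(sfs, function(s) surv_u(0.05, s))) > 0))
})

test_that("degenerate-denominator limits join the generic branch smoothly", {
  # T_v = T_a untreated makes C = 0; delta tuned so A ~ C triggers the limit
  mk <- function(delta) kinetic_parameters(delta, 0.5, T_u = 5, T_v = 7,
                                           T_a = 7, T_h = 1, SF_u = 0.9,
                                           SF_v = 0.9)
  exact_deg <- advance_one_day(compartment_state(1, 1, 0), mk(0), FALSE)
  near_deg <- advance_one_day(compartment_state(1, 1, 0), mk(1e-10), FALSE)
  off_deg <- advance_one_day(compartment_state(1, 1, 0), mk(1e-6), FALSE)
  expect_equal(unname(near_deg), unname(exact_deg), tolerance = 1e-8)
  expect_equal(unname(off_deg), unname(exact_deg), tolerance = 1e-5)
  # Euler agrees in the exactly-degenerate case too
  num <- euler_integrate(compartment_state(1, 1, 0), mk(0), FALSE,
                         substeps = 2e4)
  expect_equal(c(num$U[2], num$V[2], num$W[2]), unname(exact_deg),
               tolerance = 1e-4)
})
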