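test_that("the objective matches its definition on simple cases", {
  course <- monday_course()
  pars <- squamous_params()
  sim <- simulate_course(pars, course)
  # measured == modelled => R = 0
  course$volume_cm3[course$imaging] <- 120 * sim$total_norm[course$imaging]
  # R scales as the square root of the deviation, so float dust appears
  # at the ~1e-8 level
  expect_lt(objective_r(pars, course), 1e-7)

  # hand-computable: perturb one day by a known normalized offset
  vols <- volume_series(course)
  n <- nrow(vols)
  vols$volume_cm3[10] <- vols$volume_cm3[10] + 0.05 * 120
  expect_equal(objective_r(pars, course, vols), sqrt(0.05 / n),
               tolerance = 1e-9)
  # rms variant on the same data
  expect_equal(objective_r(pars, course, vols, variant = "rms"),
               sqrt(0.05^2 / n), tolerance = 1e-9)

  # rescaling all volumes leaves R unchanged
  vols2 <- vols
  vols2$volume_cm3 <- vols2$volume_cm3 * 3.7
  expect_equal(objective_r(pars, course, vols2),
               objective_r(pars, course, vols), tolerance = 1e-12)

  # dates outside the course are rejected
  bad <- vols
  bad$date[5] <- max(course$date) + 30
  expect_error(objective_r(pars, course, bad), class = "csck_config_error")
})

test_that("percent-error statistics use the sample convention", {
  out <- percent_error_stats(c(1, 1), c(1.02, 1.04))
  expect_equal(out$mean_pct, 3)
  expect_equal(out$sd_pct, sd(c(2, 4)))
  expect_equal(percent_error_stats(c(1, 0.9), c(1, 0.9))$mean_pct, 0)
  expect_error(percent_error_stats(1:3, 1:2), class = "csck_config_error")
})

test_that("noiseless synthetic volumes are recovered near-exactly", {
  truth <- recovery_truth()
  crs <- generate_volumes(synthetic_spec(truth = truth, preset = "squamous",
                                         noise_sd = 0, seed = 1))
  # self-consistency: the objective vanishes at the generating parameters
  expect_lt(objective_r(truth, crs), 1e-6)

  fit <- fit_parameters(crs, preset = "squamous")
  est <- setNames(fit$estimate$estimate, fit$estimate$term)
  expect_lt(abs(est[["delta"]] - 0.03), 0.005)
  expect_lt(abs(est[["p"]] - 0.25), 0.02)
  expect_lt(abs(est[["SF_u"]] - 0.98), 0.005)
  expect_lt(abs(est[["T_h"]] - 1.0), 0.3)
  expect_lt(fit$R, 1e-4)
  expect_lt(fit$percent_errors$mean, 0.1)
  # reported SF_v satisfies the mixing relation at the estimate
  expect_lt(abs(sf_total(est[["p"]], est[["SF_u"]], est[["SF_v"]]) - 0.90),
            1e-9)
})

test_that("the optimum beats random feasible parameter draws", {
  truth <- recovery_truth()
  crs <- generate_volumes(synthetic_spec(truth = truth, preset = "squamous",
                                         noise_sd = 0, seed = 2))
  fit <- fit_parameters(crs, preset = "squamous")
  set.seed(123)
  n_better <- 0L
  for (i in 1:1000) {
    delta <- runif(1, 0.001, 0.2); p <- runif(1, 0.001, 0.999)
    SF_u <- runif(1, 0.001, 1); T_h <- runif(1, 0.1, 20)
    sf_v <- (0.90 - p * SF_u) / (1 - p)
    if (sf_v <= 0 || sf_v > 1) next
    pars <- kinetic_parameters(delta, p, T_u = 6.2, T_h = T_h,
                               SF_u = SF_u, SF_v = sf_v)
    if (objective_r(pars, crs) < fit$R) n_better <- n_better + 1L
  }
  expect_identical(n_better, 0L)
})

test_that("tidy, glance and reports expose the fit", {
  truth <- recovery_truth()
  crs <- generate_volumes(synthetic_spec(truth = truth, preset = "squamous",
                                         noise_sd = 0.03, seed = 5))
  fit <- fit_parameters(crs, preset = "squamous")
  td <- tidy(fit)
  expect_identical(td$term, c("delta", "p", "SF_u", "SF_v", "T_h"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n, 33L)
  expect_gte(gl$R, 0)

  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fit, json, csv)
  rep <- jsonlite::fromJSON(json)
  expect_equal(rep$estimate$p, td$estimate[td$term == "p"], tolerance = 1e-9)
  tr <- read.csv(csv)
  expect_identical(nrow(tr), nrow(crs))

  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("stability scans slice the objective one parameter at a time", {
  truth <- recovery_truth()
  crs <- generate_volumes(synthetic_spec(truth = truth, preset = "squamous",
                                         noise_sd = 0, seed = 1))
  fit <- fit_parameters(crs, preset = "squamous")
  est <- setNames(fit$estimate$estimate, fit$estimate$term)

  # the scan at the estimate's own value reproduces the fit's R
  sc <- stability_scan(fit, "p", grid = c(0.1, est[["p"]], 0.6))
  expect_equal(sc$R[2], fit$R, tolerance = 1e-9)

  # unique minimum at the generating value for p and SF_u
  for (par in c("p", "SF_u")) {
    scan <- stability_scan(fit, par)
    truth_val <- if (par == "p") 0.25 else 0.98
    i <- which.min(scan$R)
    step <- diff(scan$value[1:2])
    expect_lt(abs(scan$value[i] - truth_val), step + 1e-9)
    # unimodal: R non-increasing left of the argmin, non-decreasing right
    expect_true(all(diff(scan$R[seq_len(i)]) <= 1e-9))
    expect_true(all(diff(scan$R[i:nrow(scan)]) >= -1e-9))
  }

  # delta is the sensitive direction: per unit parameter change the
  # objective rises faster along delta than along p near the optimum
  sc_d <- stability_scan(fit, "delta")
  sc_p <- stability_scan(fit, "p")
  slope <- function(sc) {
    i <- which.min(sc$R)
    j <- min(i + 5L, nrow(sc))
    (sc$R[j] - sc$R[i]) / (sc$value[j] - sc$value[i])
  }
  expect_gt(slope(sc_d), slope(sc_p))

  expect_error(stability_scan(fit, "T_h"))
  expect_s3_class(autoplot(sc_d), "ggplot")
})

test_that("the generating doubling time wins the model comparison", {
  truth <- recovery_truth()   # generated with T = T_pot = 6.2 d
  crs <- generate_volumes(synthetic_spec(truth = truth, preset = "squamous",
                                         noise_sd = 0.03, seed = 8))
  cmp <- doubling_time_comparison(crs, preset = "squamous")
  expect_identical(cmp$doubling_time, c("T_pot", "T_div", "T_vol"))
  expect_lte(cmp$R[cmp$doubling_time == "T_pot"],
             cmp$R[cmp$doubling_time == "T_div"])
  expect_lte(cmp$R[cmp$doubling_time == "T_pot"],
             cmp$R[cmp$doubling_time == "T_vol"])
})

test_that("a short division time produces weekend regrowth spikes", {
  # in-vitro division time (0.92 d) in place of T_pot: zigzag trajectory
  ad <- histology_preset("adenocarcinoma")
  pars <- patient_kinetic_parameters("A1", T_days = ad$T_div)
  sim <- simulate_course(pars, monday_course())
  # every Monday burden exceeds the preceding Saturday's
  mondays <- which(format(sim$date, "%u") == "1")[-1]
  expect_true(all(sim$total_norm[mondays] > sim$total_norm[mondays - 2]))
  # whereas with T_pot any weekend regrowth stays below contouring noise
  sim_pot <- simulate_course(patient_kinetic_parameters("A1"),
                             monday_course())
  expect_true(all(diff(sim_pot$total_norm) <= 0.005))
})
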