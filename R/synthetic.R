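# Synthetic CBCT-like volume series.  The study's per-patient daily
# volume measurements were never deposited, so end-to-end testing of the
# fitting machinery runs on series generated by the forward model itself
# plus multiplicative lognormal measurement noise (contouring error scales
# with volume and volumes are positive).

#' Specify a synthetic treatment course and volume series
#'
#' Bundles the ground-truth kinetic parameters, histology preset, calendar
#' settings and noise level from which [generate_volumes()] simulates a
#' patient-like daily volume series. Defaults emulate the study conditions:
#' 33 weekday fractions, one CBCT volume per fraction day, baseline volume
#' in the range of the study's gross tumor volumes, and 3% multiplicative
#' measurement noise.
#'
#' @param truth A [kinetic_parameters()] ground truth. Its `SF_v` must be
#'   consistent with the preset's population surviving fraction (within
#'   `1e-6`); supply `SF_v = NULL` in `truth_args` style by passing a truth
#'   built with [solve_sf_v()].
#' @param patient Alternatively, a study patient ID (`"A1"`, ..., `"S3"`):
#'   uses that patient's fitted parameters as truth, the histology-matched
#'   preset and baseline volume, and (for `"A2"`) a one-week treatment
#'   interruption.
#' @param preset A [histology_preset()] or its name.
#' @param baseline_volume First-day tumor volume, cm^3.
#' @param n_fractions Number of 2 Gy fractions.
#' @param start_date First fraction day (weekday).
#' @param gap_after_fraction,gap_weekdays Treatment interruption, see
#'   [standard_course()].
#' @param noise_sd Fractional SD of the multiplicative lognormal
#'   measurement noise (`>= 0`; 0 gives noiseless volumes).
#' @param seed Integer RNG seed; generation is deterministic given the
#'   spec.
#' @return A list of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(patient = "S1", noise_sd = 0.03, seed = 7)
#' crs <- generate_volumes(spec)
#' @export
synthetic_spec <- function(truth = NULL, patient = NULL,
                           preset = "squamous", baseline_volume = 100,
                           n_fractions = 33,
                           start_date = as.Date("2017-01-02"),
                           gap_after_fraction = 5, gap_weekdays = 0,
                           noise_sd = 0.03, seed = 1) {
  if (!is.null(patient)) {
    row <- patient_parameters()[patient_parameters()$patient == patient, ]
    if (nrow(row) != 1L) {
      abort(sprintf("Unknown patient '%s'.", patient),
            class = "csck_config_error")
    }
    preset <- histology_preset(row$histology)
    truth <- patient_kinetic_parameters(patient)
    chars <- patient_characteristics()
    baseline_volume <- chars$gtv_cm3[chars$patient == patient]
    if (patient == "A2") {
      # one-week interruption; a Friday start plus six missed weekdays
      # reproduces the reported 55-day course span
      start_date <- as.Date("2017-01-06")
      gap_weekdays <- 6
    }
  }
  if (is.character(preset)) preset <- histology_preset(preset)
  if (is.null(truth)) {
    abort("Provide `truth` kinetic parameters or a `patient` ID.",
          class = "csck_config_error")
  }
  validate_kinetic_parameters(truth)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "csck_config_error")
  }
  if (baseline_volume <= 0) {
    abort("`baseline_volume` must be positive.", class = "csck_config_error")
  }
  implied <- sf_total(truth$p, truth$SF_u, truth$SF_v)
  if (abs(implied - preset$SF_T) > 0.005) {
    abort(sprintf(
      "Truth is infeasible under the preset: p*SF_u + (1-p)*SF_v = %.4f but SF_T = %.2f.",
      implied, preset$SF_T), class = "csck_infeasible_error")
  }
  structure(list(truth = truth, preset = preset,
                 baseline_volume = baseline_volume,
                 n_fractions = n_fractions, start_date = as.Date(start_date),
                 gap_after_fraction = gap_after_fraction,
                 gap_weekdays = gap_weekdays,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 patient = patient),
            class = "synthetic_spec")
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic volume-measured treatment course
#'
#' Simulates the forward model over the specified calendar and attaches a
#' measured volume to every imaging day:
#' `M_i = baseline_volume * (G_i / G_0) * exp(e_i)` with
#' `e_i ~ N(0, noise_sd^2)` i.i.d. Deterministic given the spec's seed;
#' the global RNG state is left untouched. Note the lognormal noise has
#' mean `exp(noise_sd^2 / 2)`, a ~0.05% upward bias at the default 3%
#' noise.
#'
#' @param spec A [synthetic_spec()].
#' @return A `treatment_course` tibble with `volume_cm3` filled on imaging
#'   days; the spec is attached as attribute `synthetic_spec` and the
#'   noise-free volumes as column `volume_true_cm3`.
#' @export
generate_volumes <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec.", class = "csck_config_error")
  }
  course <- standard_course(spec$start_date, n_fractions = spec$n_fractions,
                            gap_after_fraction = spec$gap_after_fraction,
                            gap_weekdays = spec$gap_weekdays)
  sim <- simulate_course(spec$truth, course)
  true_vol <- spec$baseline_volume * sim$total_norm
  n_img <- sum(course$imaging)
  eps <- if (spec$noise_sd > 0) {
    with_preserved_seed(spec$seed, stats::rnorm(n_img, 0, spec$noise_sd))
  } else {
    numeric(n_img)
  }
  course$volume_true_cm3 <- ifelse(course$imaging, true_vol, NA_real_)
  vols <- rep(NA_real_, nrow(course))
  vols[course$imaging] <- true_vol[course$imaging] * exp(eps)
  course$volume_cm3 <- vols
  attr(course, "synthetic_spec") <- spec
  course
}

#' A reproducible five-patient synthetic benchmark suite
#'
#' One synthetic course per study patient, using that patient's fitted
#' parameters as ground truth, the histology-matched preset and baseline
#' gross tumor volume, 33 fractions with weekday-only delivery, and a
#' one-week treatment interruption for the A2 analogue (55-day span).
#' Noise realizations differ across patients and change with `seed`;
#' calendars do not.
#'
#' @param seed Integer seed for the measurement noise.
#' @param noise_sd Fractional measurement noise SD (default 0.03).
#' @return A tibble with one row per patient: `patient`, `histology`,
#'   `baseline_volume`, list-columns `truth` ([kinetic_parameters()]) and
#'   `course` (volume-bearing `treatment_course`).
#' @examples
#' suite <- patient_like_suite(seed = 1)
#' vapply(suite$course, function(x) sum(x$imaging), numeric(1))  # 33 each
#' @export
patient_like_suite <- function(seed = 1, noise_sd = 0.03) {
  pts <- patient_parameters()$patient
  rows <- purrr::imap(pts, function(pt, i) {
    spec <- synthetic_spec(patient = pt, noise_sd = noise_sd,
                           seed = as.integer(seed) + 1000L * i)
    course <- generate_volumes(spec)
    tibble::tibble(
      patient = pt,
      histology = spec$preset$name,
      baseline_volume = spec$baseline_volume,
      truth = list(spec$truth),
      course = list(course)
    )
  })
  dplyr::bind_rows(rows)
}
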