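# Published study constants: patient characteristics, per-patient fitted
# parameters, and the NCI-H2170 cell-count assay.  These are inputs to
# consistency checks and ground truth for the synthetic-data generator;
# the raw per-day CBCT volume series behind the fits were never deposited.

#' Characteristics of the five study patients
#'
#' Stage III lung-cancer patients treated with 33 x 2 Gy IMRT and imaged
#' daily with cone-beam CT: histology, baseline gross tumor volume and
#' tumor location.
#'
#' @return A tibble with columns `patient`, `age`, `sex`, `stage`,
#'   `histology`, `gtv_cm3`, `location`.
#' @export
patient_characteristics <- function() {
  tibble::tibble(
    patient   = c("A1", "A2", "S1", "S2", "S3"),
    age       = c(77, 80, 65, 78, 80),
    sex       = c("M", "M", "F", "M", "F"),
    stage     = c("IIIA", "IIIB", "IIIA", "IIIB", "IIIA"),
    histology = c("adenocarcinoma", "adenocarcinoma",
                  "squamous", "squamous", "squamous"),
    gtv_cm3   = c(162.5, 177.1, 115.9, 77.6, 91.8),
    location  = c("LUL", "RUL", "RLL", "RUL", "RUL")
  )
}

#' Per-patient fitted kinetic parameters
#'
#' The radiobiological parameters estimated from each patient's 33 daily
#' CBCT volume measurements: symmetric-division probability `delta`, CSC
#' proportion `p`, surviving fractions `SF_u` (CSC) and `SF_v` (TC) at
#' 2 Gy, dead-cell clearance half-time `T_h` (days) and the attained
#' objective value `R`. Used as internal-consistency references and as
#' ground-truth presets for synthetic data.
#'
#' @return A tibble with columns `patient`, `histology`, `delta`, `p`,
#'   `SF_u`, `SF_v`, `T_h`, `R`.
#' @examples
#' fits <- patient_parameters()
#' mean(fits$p)  # ~0.3 across the five patients
#' @export
patient_parameters <- function() {
  tibble::tibble(
    patient   = c("A1", "A2", "S1", "S2", "S3"),
    histology = c("adenocarcinoma", "adenocarcinoma",
                  "squamous", "squamous", "squamous"),
    delta = c(0.018, 0.162, 0.024, 0.048, 0.037),
    p     = c(0.416, 0.400, 0.242, 0.235, 0.211),
    SF_u  = c(0.950, 0.942, 0.980, 0.978, 0.986),
    SF_v  = c(0.385, 0.406, 0.874, 0.876, 0.877),
    T_h   = c(1.5, 8.1, 1.1, 0.5, 0.5),
    R     = c(0.035, 0.027, 0.041, 0.067, 0.082)
  )
}

#' Kinetic parameters for one study patient
#'
#' Convenience constructor: the fitted parameter row of a patient combined
#' with the histology preset's shared doubling time.
#'
#' @param patient One of `"A1"`, `"A2"`, `"S1"`, `"S2"`, `"S3"`.
#' @param T_days Shared doubling time for `T_u = T_v = T_a`; defaults to
#'   the histology's potential doubling time.
#' @return A [kinetic_parameters()] object.
#' @export
patient_kinetic_parameters <- function(patient, T_days = NULL) {
  row <- patient_parameters()[patient_parameters()$patient == patient, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown patient '%s'.", patient),
          class = "csck_config_error")
  }
  preset <- histology_preset(row$histology)
  if (is.null(T_days)) T_days <- preset$T_pot
  kinetic_parameters(delta = row$delta, p = row$p, T_u = T_days,
                     T_h = row$T_h, SF_u = row$SF_u, SF_v = row$SF_v)
}

#' NCI-H2170 cell-count assay
#'
#' Mean counts (millions, 3 samples per day) of NCI-H2170 squamous-cell
#' lung-cancer cultures: an unirradiated control arm counted on days 2, 3,
#' 4, 6 and 9, and an arm irradiated with a single 2 Gy dose counted on
#' days 2, 6 and 9. Both arms were seeded with 1.6 million cells on day 0.
#'
#' @return A tibble with columns `day`, `count_millions`, `irradiated`
#'   (logical); the seed count is recorded in the `seed_millions`
#'   attribute.
#' @examples
#' a <- assay_counts()
#' attr(a, "seed_millions")  # 1.6
#' @export
assay_counts <- function() {
  out <- tibble::tibble(
    day = c(2, 3, 4, 6, 9, 2, 6, 9),
    count_millions = c(2.78, 3.24, 4.32, 8.27, 21.2, 2.16, 4.62, 9.38),
    irradiated = c(rep(FALSE, 5L), rep(TRUE, 3L))
  )
  attr(out, "seed_millions") <- 1.6
  out
}
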