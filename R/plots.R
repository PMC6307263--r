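# ggplot2 displays for simulated trajectories, fits, scans and assay fits.

#' Plot a simulated (or measured) course trajectory
#'
#' @param sim Output of [simulate_course()] (optionally with measured
#'   volumes in `volume_cm3`).
#' @return A ggplot: normalized modelled burden per day, fraction days
#'   marked, measured relative volumes overlaid when present.
#' @export
plot_trajectory <- function(sim) {
  p <- ggplot2::ggplot(sim, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$total_norm), linewidth = 0.4) +
    ggplot2::geom_point(
      data = sim[sim$fraction, ],
      ggplot2::aes(y = .data$total_norm), size = 0.6
    ) +
    ggplot2::labs(x = NULL, y = "Relative tumor burden G / G0",
                  title = "Modelled tumor regression") +
    ggplot2::theme_minimal()
  if (any(!is.na(sim$volume_cm3))) {
    meas <- sim[!is.na(sim$volume_cm3), ]
    meas$meas_norm <- meas$volume_cm3 / meas$volume_cm3[1L]
    p <- p + ggplot2::geom_point(
      data = meas, ggplot2::aes(y = .data$meas_norm),
      shape = 1, colour = "firebrick"
    )
  }
  p
}

#' @describeIn fit_parameters Plot measured vs modelled normalized volumes.
#' @param object An `rt_fit`.
#' @param ... Unused.
#' @method autoplot rt_fit
#' @export
autoplot.rt_fit <- function(object, ...) {
  tr <- object$trajectory
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$modelled_norm,
                                    colour = "model"), linewidth = 0.4) +
    ggplot2::geom_point(
      data = tr[!is.na(tr$measured_norm), ],
      ggplot2::aes(y = .data$measured_norm, colour = "measured"), shape = 1
    ) +
    ggplot2::scale_colour_manual(NULL, values = c(model = "black",
                                                  measured = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Relative tumor volume",
                  subtitle = sprintf("R = %.3f; fit error %.1f%% +/- %.1f%%",
                                     object$R, object$percent_errors$mean,
                                     object$percent_errors$sd)) +
    ggplot2::theme_minimal()
}

#' @describeIn stability_scan Plot the objective slice.
#' @param object A `stability_scan` tibble.
#' @param ... Unused.
#' @method autoplot stability_scan
#' @export
autoplot.stability_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$R)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object[which.min(object$R), ],
                        colour = "firebrick") +
    ggplot2::labs(x = object$parameter[1L], y = "Objective R",
                  title = "One-parameter stability scan") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_exponential Plot counts and the fitted exponential.
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(day = seq(min(dat$day), max(dat$day),
                                   length.out = 100L))
  grid$count <- object$N0 * exp(object$k * grid$day)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$count)) +
    ggplot2::geom_line(data = grid, linewidth = 0.4) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "Day", y = "Cell count (millions)",
                  subtitle = sprintf("N0 = %.3f M, k = %.4f /day",
                                     object$N0, object$k)) +
    ggplot2::theme_minimal()
}
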