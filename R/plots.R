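# ggplot2 display helpers. Cosmetic only: every plot draws from the same
# tibbles the tabular interfaces return.

#' Plot a sealed-dendrite variance profile
#'
#' @param data A tibble from [variance_profile()], optionally with extra
#'   grouping columns (e.g. one profile per `lambda`).
#' @param colour Optional name of a grouping column mapped to colour.
#' @return A ggplot object.
#' @export
plot_variance_profile <- function(data, colour = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$variance))
  if (!is.null(colour))
    p <- p + ggplot2::aes(colour = factor(.data[[colour]])) +
      ggplot2::labs(colour = colour)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "position x (um)", y = "voltage variance (mV^2)")
}

#' Plot a firing-rate sweep
#'
#' @param data A tibble with a rate column and the swept parameter.
#' @param x Name of the swept column.
#' @param y Name of the rate column (default `"rate_hz"`).
#' @param colour Optional grouping column.
#' @return A ggplot object.
#' @export
plot_rate_curve <- function(data, x, y = "rate_hz", colour = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]]))
  if (!is.null(colour))
    p <- p + ggplot2::aes(colour = factor(.data[[colour]])) +
      ggplot2::labs(colour = colour)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = x, y = "rate (Hz)")
}

#' Plot the trigger-point voltage spectrum
#'
#' @param data A tibble from [spectrum_table()].
#' @return A ggplot object (log-log axes).
#' @export
plot_spectrum <- function(data) {
  ggplot2::ggplot(data[data$omega > 0, ],
                  ggplot2::aes(x = .data$omega, y = .data$S)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "angular frequency (rad/ms)", y = "S(omega) (mV^2 ms)")
}

#' Autoplot a simulation
#'
#' Shows the trigger-voltage trace (if recorded) with threshold and spike
#' marks, or the spike raster otherwise.
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cable_sim <- function(object, ...) {
  v_th <- object$lattice$morph$threshold$v_th
  if (!is.null(object$trace)) {
    df <- tibble(time = seq_along(object$trace) * object$dt,
                 v = as.numeric(object$trace))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$v)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = v_th, linetype = "dashed") +
      ggplot2::labs(x = "time (ms)", y = "voltage at trigger (mV)")
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = 0)) +
      ggplot2::geom_point(shape = "|", size = 4) +
      ggplot2::labs(x = "time (ms)", y = NULL)
  }
}
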