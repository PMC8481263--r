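#' Plot a spectrum layer with smoothing and baseline
#'
#' @param layer one layer tibble of a record (columns `calibration`,
#'   `counts`, `smoothed_counts`, `baseline`).
#' @param window optional energy window to zoom into, MeV.
#' @return a ggplot.
#' @export
plot_spectrum <- function(layer, window = NULL) {
  d <- layer
  if (!is.null(window))
    d <- d |> dplyr::filter(.data$calibration >= window[1],
                            .data$calibration < window[2])
  ggplot(d, aes(x = .data$calibration)) +
    geom_step(aes(y = .data$counts), colour = "grey55") +
    geom_line(aes(y = .data$smoothed_counts), colour = "#2166ac") +
    geom_line(aes(y = .data$baseline), colour = "#b2182b",
              linetype = "dashed") +
    labs(x = "Energy (MeV)", y = "Counts per bin")
}

#' @describeIn detect_campaign F value versus distance to the phantom end,
#'   with the critical value as a horizontal reference (the detection
#'   pattern figure).
#' @param object a `pg_detection_report`.
#' @param ... unused.
#' @export
autoplot.pg_detection_report <- function(object, ...) {
  ggplot(object, aes(x = .data$d_end, y = .data$f_value,
                     shape = .data$reject, colour = .data$target_region)) +
    geom_hline(aes(yintercept = .data$f_critical), linetype = "dashed") +
    geom_point(size = 2.5) +
    scale_y_log10() +
    scale_x_reverse() +
    labs(x = "Distance to phantom end (cm)", y = "F value",
         colour = "Target", shape = "Rejected")
}

#' @describeIn fit_range_model the calibration line over the fitted points.
#' @param object a `pg_range_model`.
#' @export
autoplot.pg_range_model <- function(object, ...) {
  ggplot(object$data, aes(x = .data$d_end, y = .data$area)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "#2166ac") +
    scale_x_reverse() +
    labs(x = "Distance to phantom end (cm)", y = "Silicon peak area")
}

#' @describeIn fit_restricted window data with the fitted model and its
#'   components.
#' @param object a `pg_peak_fit`.
#' @export
autoplot.pg_peak_fit <- function(object, ...) {
  grid <- tibble::tibble(
    energy = seq(object$window[1], object$window[2], length.out = 400))
  grid$fitted <- predict(object, grid$energy)
  ggplot(object$data, aes(x = .data$energy, y = .data$counts)) +
    geom_point(colour = "grey40") +
    geom_line(data = grid, aes(y = .data$fitted), colour = "#b2182b") +
    labs(x = "Energy (MeV)", y = "Counts per bin")
}
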