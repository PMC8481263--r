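#' Fit an energy calibration curve
#'
#' Least-squares polynomial from uncalibrated bin position to energy (MeV),
#' anchored on known lines -- the 0.6617 MeV Cs-137 reference plus oxygen
#' lines for nonlinearity correction. Two anchors give a straight line,
#' three or more a quadratic; higher degrees are deliberately rejected (the
#' nonlinearity is a mild correction, and high-degree polynomials
#' oscillate). The fitted map must be strictly increasing over the bin
#' range.
#'
#' @param anchors data frame with columns `bin` and `energy_mev`.
#' @param degree polynomial degree; default 1 with two anchors, 2 otherwise,
#'   capped at 2.
#' @param bin_range bin interval over which monotonicity is required.
#' @param anchor_tol warn if any anchor residual exceeds this (MeV).
#' @return An object of class `pg_calibration` with `coefficients`
#'   (ascending powers), `degree`, `anchors`, `bin_range`, `residuals`.
#' @export
fit_calibration <- function(anchors, degree = NULL,
                            bin_range = c(0, 2047), anchor_tol = 0.01) {
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) < 2) abort("need at least 2 calibration anchors")
  if (anyDuplicated(anchors$bin)) abort("duplicate anchor bin positions")
  if (is.null(degree)) degree <- if (nrow(anchors) >= 3) 2L else 1L
  if (degree > 2) abort("calibration degree is capped at 2")
  if (nrow(anchors) < degree + 1)
    abort("not enough anchors for the requested degree")
  fit <- lm(energy_mev ~ poly(bin, degree, raw = TRUE), data = anchors)
  coefs <- unname(coef(fit))
  # derivative of a degree <= 2 polynomial is linear: check the endpoints
  dpoly <- function(b) {
    if (degree == 1) coefs[2] else coefs[2] + 2 * coefs[3] * b
  }
  if (dpoly(bin_range[1]) <= 0 || dpoly(bin_range[2]) <= 0)
    abort("fitted calibration is not strictly increasing over the bin range")
  res <- unname(stats::residuals(fit))
  if (max(abs(res)) > anchor_tol)
    warn(sprintf("calibration anchor residual %.4g MeV exceeds tolerance %g",
                 max(abs(res)), anchor_tol))
  structure(list(coefficients = coefs, degree = degree,
                 anchors = tibble::as_tibble(anchors),
                 bin_range = bin_range, residuals = res),
            class = "pg_calibration")
}

#' Apply an energy calibration to bin positions
#'
#' @param cal a [fit_calibration()] result.
#' @param bins numeric bin positions.
#' @return energies in MeV (strictly increasing for increasing bins).
#' @export
apply_calibration <- function(cal, bins) {
  stopifnot(inherits(cal, "pg_calibration"))
  out <- rep(cal$coefficients[1], length(bins))
  for (d in seq_len(cal$degree)) out <- out + cal$coefficients[d + 1] * bins^d
  out
}

#' Savitzky-Golay spectrum smoothing
#'
#' Local polynomial least-squares smoothing; inputs that are polynomials of
#' degree `poly_order` or less are reproduced exactly. Defaults (window 9,
#' order 3) preserve the roughly 10-bin-wide peaks of the default 4 keV
#' binning.
#'
#' @param counts numeric spectrum.
#' @param window_length odd filter window length.
#' @param poly_order polynomial order, `< window_length`.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_spectrum <- function(counts, window_length = 9, poly_order = 3) {
  if (window_length %% 2 != 1) abort("`window_length` must be odd")
  if (poly_order >= window_length)
    abort("`poly_order` must be smaller than `window_length`")
  as.numeric(signal::sgolayfilt(as.numeric(counts), p = poly_order,
                                n = window_length))
}

#' SNIP baseline estimate
#'
#' Statistics-sensitive Nonlinear Iterative Peak clipping: the spectrum is
#' mapped through the double-log square-root (LLS) operator, then clipped
#' against the mean of its neighbours at decreasing window half-widths from
#' `iterations` down to 1, and mapped back. Only minimum operations are
#' applied, so the baseline never exceeds the input; away from peaks it
#' tracks the spectrum, under a peak it interpolates the surrounding
#' continuum.
#'
#' @param counts non-negative spectrum.
#' @param iterations largest clipping half-width in bins (24 by default,
#'   comfortably wider than the peak half-widths at 4 keV binning).
#' @return baseline vector, `0 <= baseline <= counts`.
#' @export
snip_baseline <- function(counts, iterations = 24) {
  y <- pmax(as.numeric(counts), 0)
  n <- length(y)
  v <- log(log(sqrt(y + 1) + 1) + 1)
  for (m in seq(min(iterations, n %/% 2), 1)) {
    i <- (m + 1):(n - m)
    v[i] <- pmin(v[i], (v[i - m] + v[i + m]) / 2)
  }
  b <- (exp(exp(v) - 1) - 1)^2 - 1
  pmax(pmin(b, y), 0)
}

#' Apply low/high energy thresholds to a spectrum
#'
#' Bins with centre energy outside `[low_mev, high_mev)` (inclusive left,
#' exclusive right) have their counts zeroed; the number of surviving bins
#' is attached as attribute `n_surviving`.
#'
#' @param spectrum data frame with `energy` and `counts` columns.
#' @param low_mev,high_mev threshold energies, `low_mev < high_mev`.
#' @return `spectrum` with out-of-window counts zeroed.
#' @export
apply_energy_thresholds <- function(spectrum, low_mev, high_mev) {
  if (low_mev >= high_mev) abort("`low_mev` must be below `high_mev`")
  if (is.null(spectrum[["energy"]]) || is.null(spectrum[["counts"]]))
    abort("`spectrum` must have `energy` and `counts` columns")
  keep <- spectrum$energy >= low_mev & spectrum$energy < high_mev
  out <- spectrum
  out$counts[!keep] <- 0
  attr(out, "n_surviving") <- sum(keep)
  out
}
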