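#' Monte Carlo null distribution of the silicon F statistic
#'
#' Simulates analysis windows containing only the oxygen line -- a constant
#' background plus a single 1.635 MeV Cauchy-Lorentz peak with additive
#' Gaussian noise -- fits the restricted and unrestricted models to each,
#' and returns the F values. Used to check the type-I error of the
#' detection test at the operating significance level and to compare the
#' statistic's empirical distribution with its nominal F reference.
#'
#' The fits run through the same compiled Levenberg-Marquardt core as
#' [test_silicon()], with the unrestricted fit warm-started from the
#' restricted solution so nesting holds on every window.
#'
#' @param n_sim number of simulated windows.
#' @param window energy window, MeV (65 points on the default axis).
#' @param constant background level, counts per bin.
#' @param oxygen_amplitude oxygen line peak height, counts per bin.
#' @param oxygen_mean,oxygen_scale oxygen line centroid (MeV) and half width
#'   at half maximum.
#' @param noise_sd Gaussian noise standard deviation, counts per bin.
#' @param silicon_amplitude silicon line height injected into the truth
#'   (0 = null; positive values give power studies).
#' @param silicon_mean,silicon_scale silicon line parameters.
#' @param seed integer seed.
#' @param mean_box,scale_bounds,ftol,max_iter fit controls (see
#'   [fit_restricted()]); the batch default `ftol = 1e-8` resolves SSR far
#'   beyond the noise scale.
#' @param chunk_size windows simulated per block (memory control).
#' @return tibble with `f_value`, `ssr_r`, `ssr_ur`, plus attributes `q`,
#'   `df_ur`, `n` (window points).
#' @examples
#' f0 <- simulate_null_f_values(200, seed = 1)
#' mean(f0$f_value > f_critical(0.05, 3, attr(f0, "df_ur")))
#' @export
simulate_null_f_values <- function(n_sim, window = c(1.58, 1.84),
                                   constant = 100, oxygen_amplitude = 300,
                                   oxygen_mean = 1.635,
                                   oxygen_scale = 0.0285, noise_sd = 10,
                                   silicon_amplitude = 0,
                                   silicon_mean = 1.78,
                                   silicon_scale = 0.031, seed = NULL,
                                   mean_box = 0.05, scale_bounds = NULL,
                                   ftol = 1e-8, max_iter = 300,
                                   chunk_size = 10000) {
  axis <- energy_axis(spectrum_model())
  e <- axis[axis >= window[1] & axis < window[2]]
  n <- length(e)
  truth <- constant +
    oxygen_amplitude * oxygen_scale^2 /
      ((e - oxygen_mean)^2 + oxygen_scale^2) +
    silicon_amplitude * silicon_scale^2 /
      ((e - silicon_mean)^2 + silicon_scale^2)
  if (is.null(scale_bounds))
    scale_bounds <- default_scale_bounds(
      e, 0.5 * 0.0349 * min(oxygen_mean, silicon_mean))
  ssr <- with_seed_(seed, {
    out <- matrix(0, n_sim, 2)
    done <- 0
    while (done < n_sim) {
      m <- min(chunk_size, n_sim - done)
      Y <- matrix(truth + rnorm(n * m, 0, noise_sd), nrow = n)
      out[done + seq_len(m), ] <- lorentz_ftest_batch_cpp(
        e, Y, oxygen_mean, oxygen_scale, silicon_mean, silicon_scale,
        mean_box, scale_bounds[1], scale_bounds[2], max_iter, ftol)
      done <- done + m
    }
    out
  })
  q <- 3L
  df_ur <- n - 7L
  res <- tibble::tibble(
    ssr_r = ssr[, 1], ssr_ur = ssr[, 2],
    f_value = f_statistic(ssr[, 1], ssr[, 2], q, df_ur))
  attr(res, "q") <- q
  attr(res, "df_ur") <- df_ur
  attr(res, "n") <- n
  res
}

#' Measure the detector resolution from a synthetic calibration run
#'
#' Generates a Cs-137 calibration spectrum with [simulate_calibration_spectrum()],
#' fits the 0.6617 MeV photopeak with a single Cauchy-Lorentz plus constant
#' in a window around the line, and reports the fractional FWHM in percent
#' with its delta-method standard error ([resolution_estimate()]).
#'
#' @inheritParams simulate_calibration_spectrum
#' @param window fit window around the photopeak, MeV.
#' @return one-row tibble: `fwhm_pct`, `se_pct`, `mean_mev`, `scale_mev`,
#'   `peak_counts`.
#' @examples
#' measure_resolution(seed = 1)
#' @export
measure_resolution <- function(model = spectrum_model(), peak_counts = 3e5,
                               continuum_level = 50, seed = NULL,
                               window = c(0.58, 0.76)) {
  spec <- simulate_calibration_spectrum(model, peak_counts,
                                        continuum_level, seed)
  win <- extract_window(spec, window)
  fit <- fit_restricted(win, init_mean = 0.6617,
                        init_scale = 0.5 * model$resolution_fwhm * 0.6617)
  resolution_estimate(fit) |>
    dplyr::mutate(peak_counts = peak_counts)
}
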