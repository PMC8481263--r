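test_that("calibration fitting recovers known polynomial maps", {
  # two anchors: straight line through both
  cal <- fit_calibration(data.frame(bin = c(100, 1000),
                                    energy_mev = c(0.4, 4.0)))
  expect_equal(cal$degree, 1L)
  expect_equal(apply_calibration(cal, c(100, 1000)), c(0.4, 4.0))
  # quadratic truth sampled at 4 anchors is recovered to 1e-6 relative
  true_c <- c(0.01, 0.0039, 2e-8)
  bins <- c(50, 400, 1100, 1900)
  e <- true_c[1] + true_c[2] * bins + true_c[3] * bins^2
  cal2 <- fit_calibration(data.frame(bin = bins, energy_mev = e))
  expect_equal(cal2$degree, 2L)
  expect_equal(cal2$coefficients, true_c, tolerance = 1e-6)
  # anchors on a straight line leave a vanishing quadratic term
  e_lin <- 0.002 + 0.004 * bins
  cal3 <- fit_calibration(data.frame(bin = bins, energy_mev = e_lin))
  expect_lt(abs(cal3$coefficients[3]) * 2047^2, 1e-6)
  # degenerate anchor sets are refused
  expect_error(fit_calibration(data.frame(bin = 1, energy_mev = 0.5)),
               "at least 2")
  expect_error(fit_calibration(data.frame(bin = c(1, 1),
                                          energy_mev = c(0.5, 0.6))),
               "duplicate")
  expect_error(fit_calibration(data.frame(bin = bins, energy_mev = e),
                               degree = 3), "capped")
})

test_that("calibration output is strictly increasing and verifiable", {
  cal <- fit_calibration(data.frame(bin = c(164.75, 408.25, 444.5),
                                    energy_mev = c(0.6617, 1.635, 1.78)))
  en <- apply_calibration(cal, 0:2047)
  expect_true(all(diff(en) > 0))
  # a verification line at the silicon energy maps within one resolution
  # width of 1.78 MeV
  expect_lt(abs(apply_calibration(cal, 444.5) - 1.78), 0.0349 * 1.78)
  # a non-monotone map is rejected
  expect_error(
    fit_calibration(data.frame(bin = c(0, 10, 2000),
                               energy_mev = c(0.1, 2.0, 2.05))),
    "strictly increasing")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  x <- seq_len(200)
  quad <- 3 + 0.05 * x + 0.002 * x^2
  expect_equal(smooth_spectrum(quad, 9, 3), quad, tolerance = 1e-8)
  cubic <- 1 + 0.01 * x - 1e-4 * x^2 + 1e-6 * x^3
  expect_equal(smooth_spectrum(cubic, 9, 3), cubic, tolerance = 1e-8)
  expect_equal(smooth_spectrum(rep(7, 100), 9, 3), rep(7, 100))
  # white noise loses variance
  set.seed(12)
  noise <- rnorm(3000)
  expect_lt(var(smooth_spectrum(noise, 9, 3)), 0.7 * var(noise))
  expect_error(smooth_spectrum(noise, 8, 3), "odd")
  expect_error(smooth_spectrum(noise, 9, 9), "smaller")
})

test_that("smoothing commutes with windowing away from the boundaries", {
  set.seed(13)
  y <- 50 + rnorm(2048)
  full <- smooth_spectrum(y, 9, 3)[201:400]
  windowed <- smooth_spectrum(y[181:420], 9, 3)[21:220]
  expect_equal(full, windowed, tolerance = 1e-10)
})

test_that("SNIP baseline matches a brute-force clipping oracle", {
  set.seed(14)
  n <- 256
  flat <- rep(80, n)
  # narrow Gaussian peak: isolated structure well inside the clip window
  peak <- 400 * exp(-(seq_len(n) - 128)^2 / (2 * 3^2))
  y <- flat + peak
  b <- snip_baseline(y, 24)
  expect_equal(b, snip_reference(y, 24), tolerance = 1e-12)
  # baseline never exceeds the spectrum
  expect_true(all(b <= y + 1e-9))
  # under the peak the baseline stays within 5% of the true background
  under <- abs(seq_len(n) - 128) < 10
  expect_lt(max(abs(b[under] - 80)) / 80, 0.05)
  # a flat spectrum is its own baseline within 1%
  bf <- snip_baseline(flat, 24)
  expect_lt(max(abs(bf - flat)) / 80, 0.01)
  # an all-zero spectrum gives an all-zero baseline
  expect_equal(snip_baseline(rep(0, n), 24), rep(0, n))
})

test_that("SNIP is insensitive to a distant narrow peak", {
  n <- 1024
  base <- 60 + 20 * sin(seq_len(n) / 200)
  b0 <- snip_baseline(base, 24)
  b1 <- snip_baseline(base + lorentz_shape(seq_len(n), 500, 900, 4), 24)
  far <- seq_len(n) < 700
  expect_lt(max(abs(b1[far] - b0[far])) / max(b0[far]), 0.01)
})

test_that("energy thresholds zero the right bins", {
  model <- spectrum_model()
  spec <- tibble::tibble(energy = energy_axis(model),
                         counts = rep(1, model$bin_count))
  # the analysis window holds 65 bins on the default 4 keV axis
  out <- apply_energy_thresholds(spec, 1.58, 1.84)
  expect_equal(attr(out, "n_surviving"), 65L)
  expect_equal(sum(out$counts), 65)
  # thresholds beyond the axis: identity
  all_in <- apply_energy_thresholds(spec, -1, 100)
  expect_equal(all_in$counts, spec$counts)
  # low threshold at the axis top: nothing survives
  none <- apply_energy_thresholds(spec, max(spec$energy) + 0.004, 100)
  expect_equal(attr(none, "n_surviving"), 0L)
  expect_error(apply_energy_thresholds(spec, 2, 1), "below")
})
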