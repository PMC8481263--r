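test_that("window extraction counts 65 observations on the default axis", {
  spec <- tibble::tibble(energy = energy_axis(), counts = 1)
  win <- extract_window(spec)
  expect_equal(nrow(win), 65L)
  expect_true(all(win$energy >= 1.58 & win$energy < 1.84))
  expect_error(extract_window(spec, c(1.7, 1.7)), "positive width")
  expect_error(extract_window(spec, c(-2, -1)), "outside")
  # archive layers expose the energy axis as `calibration`
  rec <- simulate_spectrum_record(100.46, 0, seed = 1)
  expect_equal(nrow(extract_window(rec$layers$All)), 65L)
})

test_that("noiseless windows are recovered exactly by both fits", {
  win <- make_window(constant = 120, a_ox = 400)
  fr <- fit_restricted(win)
  expect_equal(fr$constant, 120, tolerance = 1e-4)
  expect_equal(fr$components$amplitude, 400, tolerance = 1e-4)
  expect_equal(fr$components$mean, 1.635, tolerance = 1e-6)
  expect_equal(fr$components$scale, 0.0285, tolerance = 1e-4)
  expect_lt(fr$ssr, 1e-6)
  # pure constant data: vanishing amplitude and SSR
  flat <- make_window(constant = 55, a_ox = 0)
  frf <- fit_restricted(flat)
  expect_lt(abs(frf$components$amplitude), 1e-3)
  expect_lt(frf$ssr, 1e-6)
  # two-line data: both components recovered
  win2 <- make_window(constant = 80, a_ox = 350, a_si = 180)
  fu <- fit_unrestricted(win2)
  amp <- setNames(fu$components$amplitude, fu$components$term)
  expect_equal(amp[["oxygen"]], 350, tolerance = 1e-3)
  expect_equal(amp[["silicon"]], 180, tolerance = 1e-3)
  expect_lt(fu$ssr, 1e-4)
})

test_that("fits agree with an independent nonlinear least-squares oracle", {
  for (seed in c(3, 4)) {
    win <- make_window(constant = 100, a_ox = 300, a_si = 120,
                       noise_sd = 10, seed = seed)
    fu <- fit_unrestricted(win)
    oracle <- minpack.lm::nlsLM(
      counts ~ c0 + A1 * s1^2 / ((energy - m1)^2 + s1^2) +
        A2 * s2^2 / ((energy - m2)^2 + s2^2),
      data = win,
      start = list(c0 = 100, A1 = 300, m1 = 1.635, s1 = 0.0285,
                   A2 = 120, m2 = 1.78, s2 = 0.031),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14))
    expect_equal(fu$ssr, sum(resid(oracle)^2), tolerance = 1e-4)
    est <- coef(oracle)
    amp <- setNames(fu$components$amplitude, fu$components$term)
    expect_equal(amp[["silicon"]], unname(est["A2"]), tolerance = 0.01)
  }
})

test_that("nesting holds on every fitted window", {
  for (seed in 1:20) {
    win <- make_window(constant = 100, a_ox = 300,
                       a_si = sample(c(0, 50), 1), noise_sd = 10,
                       seed = seed)
    ft <- test_silicon(win)
    expect_lte(ft$ssr_ur, ft$ssr_r)
    expect_gte(ft$f_value, 0)
  }
})

test_that("silicon amplitude scales linearly in the fit", {
  w1 <- make_window(a_si = 80, noise_sd = 5, seed = 7)
  w2 <- make_window(a_si = 160, noise_sd = 5, seed = 7)
  a1 <- fit_unrestricted(w1)$components$amplitude[2]
  a2 <- fit_unrestricted(w2)$components$amplitude[2]
  expect_equal(a2 / a1, 2, tolerance = 0.15)
})

test_that("the F statistic follows its closed form and conventions", {
  expect_equal(f_statistic(130, 100, 3, 58), 5.8)
  expect_equal(f_statistic(100, 100, 3, 58), 0)
  expect_warning(f0 <- f_statistic(99, 100, 3, 58), "clamped")
  expect_equal(f0, 0)
  expect_warning(fi <- f_statistic(10, 0, 3, 58), "infinite")
  expect_true(is.infinite(fi))
  # degrees of freedom from a 65-point window with 7 parameters
  ft <- test_silicon(make_window(noise_sd = 5, seed = 2))
  expect_equal(ft$n, 65L)
  expect_equal(ft$q, 3L)
  expect_equal(ft$df_ur, 58L)
  # printed-convention override
  ft49 <- test_silicon(make_window(noise_sd = 5, seed = 2), df_ur = 49)
  expect_equal(ft49$df_ur, 49)
  expect_equal(ft49$f_critical, qf(1 - 1e-4, 3, 49))
})

test_that("F critical values match an independent quantile inversion", {
  # quadrature + bisection oracle for the F(3, 58) quantile
  fcdf <- function(q) integrate(function(t) df(t, 3, 58), 0, q,
                                rel.tol = 1e-10)$value
  oracle <- uniroot(function(q) fcdf(q) - 0.95, c(0.1, 50), tol = 1e-9)$root
  expect_equal(f_critical(0.05, 3, 58), oracle, tolerance = 1e-6)
  # median below the mean for df_ur > 2
  expect_lt(f_critical(0.5, 3, 58), 58 / 56)
  # quantile increases as alpha decreases
  alphas <- c(0.1, 0.01, 1e-3, 1e-4)
  crits <- vapply(alphas, f_critical, numeric(1), q = 3, df_ur = 58)
  expect_true(all(diff(crits) > 0))
  expect_error(f_critical(0), "alpha")
  expect_error(f_critical(1), "alpha")
})

test_that("detection separates silicon-bearing from oxygen-only spectra", {
  strong <- simulate_spectrum_record(115.55, 1, seed = 42)
  ft1 <- test_silicon(strong$layers$All)
  expect_true(ft1$reject)
  expect_gt(ft1$f_value, ft1$f_critical)
  null <- simulate_spectrum_record(94.54, 0, seed = 43)
  ft0 <- test_silicon(null$layers$All)
  expect_false(ft0$reject)
  # tidy/glance expose all intermediates
  td <- tidy(ft1)
  expect_true(all(c("ssr_r", "ssr_ur", "q", "df_ur", "f_value",
                    "f_critical", "alpha", "reject") %in% names(td)))
  expect_equal(glance(ft1), td)
})

test_that("lower background at equal silicon level raises F", {
  # halving the continuum under an identical silicon line should make the
  # line easier to detect -- the benefit background suppression delivers
  hi_bg <- spectrum_model()
  lo_bg <- spectrum_model(continuum_amplitude = 1400)
  f_hi <- f_lo <- numeric(8)
  for (i in seq_len(8)) {
    rh <- simulate_spectrum_record(112.25, 0.3, model = hi_bg,
                                   seed = 100 + i)
    rl <- simulate_spectrum_record(112.25, 0.3, model = lo_bg,
                                   seed = 200 + i)
    f_hi[i] <- tidy(test_silicon(rh$layers$All))$f_value
    f_lo[i] <- tidy(test_silicon(rl$layers$All))$f_value
  }
  expect_gt(mean(f_lo), mean(f_hi))
})

test_that("rejection rate grows with the injected silicon amplitude", {
  amps <- c(0, 20, 40, 80, 160)
  rates <- vapply(amps, function(a) {
    f <- simulate_null_f_values(400, silicon_amplitude = a, seed = 50 + a)
    mean(f$f_value > f_critical(1e-4, 3, attr(f, "df_ur")))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_gt(rates[5], 0.95)
})
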