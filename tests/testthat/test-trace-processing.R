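test_that("EMG pulse fits recover noiseless ground truth", {
  tr <- simulate_trace(data.frame(area = 500, mode = 60), noise_sd = 0)
  fits <- fit_pulses(tr)
  expect_equal(nrow(fits), 1L)
  expect_false(fits$discarded)
  expect_equal(fits$area, 500, tolerance = 0.02)
  expect_equal(fits$mode, 60, tolerance = 0.5)
  expect_equal(fits$height, tr$truth$height, tolerance = 0.02)
})

test_that("EMG recovery error shrinks with the noise level", {
  err <- vapply(c(2, 0.5, 0.05), function(sd) {
    tr <- simulate_trace(data.frame(area = 800, mode = 70), noise_sd = sd,
                         seed = 21)
    abs(fit_pulses(tr)$area - 800)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1)
})

test_that("three pulses yield three fits; clipping flags overflow", {
  tr <- simulate_trace(
    data.frame(area = c(600, 900, 500), mode = c(35, 95, 155)),
    noise_sd = 0.3, seed = 4)
  fits <- fit_pulses(tr)
  expect_equal(nrow(fits), 3L)
  expect_equal(sort(fits$mode), c(35, 95, 155), tolerance = 0.05)
  expect_false(any(fits$overflow))
  # clipped plateau at the digitizer maximum
  trc <- simulate_trace(data.frame(area = 3000, mode = 60), noise_sd = 0,
                        clip_max = 50)
  expect_true(trc$overflow)
  fitc <- fit_pulses(trc, clip_max = 50)
  expect_true(all(fitc$overflow))
  # pulses closer than the configured separation flag pile-up
  trp <- simulate_trace(data.frame(area = c(500, 500), mode = c(60, 72),
                                   sigma = c(2, 2), tau = c(4, 4)),
                        noise_sd = 0.2, seed = 5)
  near <- fit_pulses(trp, pileup_separation = 15)
  expect_equal(nrow(near), 2L)
  expect_true(all(near$pileup))
  expect_false(any(fit_pulses(trp, pileup_separation = 5)$pileup))
})

test_that("the adjusted-R2 filter applies mean - 7.5 sd", {
  r2 <- c(0.99, 0.98, 0.99, 0.10)
  out <- r2_threshold_filter(data.frame(r2_adjusted = r2))
  expect_equal(out$threshold, mean(r2) - 7.5 * sd(r2))
  expect_equal(out$accepted$r2_adjusted, r2[r2 >= out$threshold])
  # identical values: sd = 0, threshold = mean, all accepted
  same <- r2_threshold_filter(data.frame(r2_adjusted = rep(0.95, 5)))
  expect_equal(same$threshold, 0.95)
  expect_equal(nrow(same$accepted), 5L)
  # a Gaussian sample without outliers is essentially fully accepted
  set.seed(8)
  g <- r2_threshold_filter(data.frame(r2_adjusted = rnorm(5000, 0.97, 0.005)))
  expect_equal(nrow(g$accepted), 5000L)
  expect_error(r2_threshold_filter(data.frame(r2_adjusted = 0.9)),
               "at least 2")
})

test_that("in-spill selection keeps exactly the declared intervals", {
  spills <- default_spills()
  ev <- simulate_event_stream(2000, seed = 10)
  expect_identical(select_in_spill(ev, spills), ev)  # generator is in-spill
  # uniform times over a 50% duty cycle retain about half
  set.seed(11)
  fake <- tibble::tibble(time_ms = runif(20000, 0, 4800))
  one <- tibble::tibble(start = 0, end = 2400)
  kept <- nrow(select_in_spill(fake, one)) / 20000
  expect_lt(abs(kept - 0.5), 4 * sqrt(0.25 / 20000))
  expect_equal(nrow(select_in_spill(fake[0, ], one)), 0L)
  expect_error(select_in_spill(fake, one[0, ]), "no spill intervals")
})

test_that("dead-time correction follows the non-paralyzable closed form", {
  expect_equal(correct_dead_time(1234, 0), 1234)
  expect_equal(correct_dead_time(850000, 0.15), 1e6)
  expect_warning(out <- correct_dead_time(100, 0.5), "15%")
  expect_equal(out, 200)
  expect_error(correct_dead_time(10, 1), "\\[0, 1\\)")
  expect_error(correct_dead_time(10, -0.1))
  # rate form m = n / (1 - n tau)
  expect_equal(correct_dead_time(1e5, rate = 1e5, tau = 2e-6), 1e5 / 0.8)
  expect_error(correct_dead_time(1, rate = 1e6, tau = 1e-5), "< 1")
  # corrected counts never fall below observed
  obs <- c(10, 100, 1000)
  expect_true(all(correct_dead_time(obs, 0.12) >= obs))
})

test_that("event histogramming conserves counts with stated conventions", {
  edges <- c(0, 1, 2, 3)
  h <- histogram_events(rep(0.5, 100), edges)
  expect_equal(as.integer(h), c(100L, 0L, 0L))
  # interior edge goes to the right-hand bin; top edge is closed
  h2 <- histogram_events(c(1, 3), edges)
  expect_equal(as.integer(h2), c(0L, 1L, 1L))
  # conservation including out-of-range
  set.seed(3)
  v <- runif(5000, -0.5, 3.5)
  h3 <- histogram_events(v, edges)
  expect_equal(sum(h3) + attr(h3, "out_of_range"), 5000L)
  # uniform values stay within 4 sigma of equal expectation
  v4 <- runif(60000, 0, 3)
  h4 <- histogram_events(v4, edges)
  expect_true(all(abs(h4 - 20000) < 4 * sqrt(20000 * 2 / 3)))
  expect_error(histogram_events(1, c(0, 0, 1)), "strictly increasing")
})
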