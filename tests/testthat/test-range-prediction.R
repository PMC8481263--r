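make_unrestricted <- function(a_si = 150, noise_sd = 0, seed = NULL) {
  fit_unrestricted(make_window(a_si = a_si, noise_sd = noise_sd,
                               seed = seed))
}

test_that("silicon peak area matches the analytic Lorentzian integral", {
  fu <- make_unrestricted(a_si = 150)
  area <- silicon_peak_area(fu, protons = 1e9)
  comp <- fu$components[fu$components$term == "silicon", ]
  expect_equal(area$area, comp$amplitude * comp$scale * pi,
               tolerance = 1e-12)
  expect_equal(area$area_per_proton, area$area / 1e9)
  # quadrature oracle over the window; the window integral is below the
  # full-line integral and approaches it as the window widens
  num <- integrate(function(e) lorentz_shape(e, comp$amplitude, comp$mean,
                                             comp$scale),
                   fu$window[1], fu$window[2], rel.tol = 1e-10)$value
  expect_equal(area$area_window, num, tolerance = 1e-8)
  expect_lt(area$area_window, area$area)
  wide <- integrate(function(e) lorentz_shape(e, comp$amplitude, comp$mean,
                                              comp$scale),
                    comp$mean - 50, comp$mean + 50, rel.tol = 1e-10)$value
  expect_equal(wide, area$area, tolerance = 1e-3)
  # zero amplitude gives zero area
  flat <- make_unrestricted(a_si = 0)
  expect_lt(abs(silicon_peak_area(flat)$area), 1e-6)
  # the restricted model has no silicon component
  fr <- fit_restricted(make_window())
  expect_error(silicon_peak_area(fr), "unrestricted")
})

test_that("the range model recovers an exact linear law", {
  pts <- tibble::tibble(d_end = c(4.6, 4.4, 3.9, 3.4),
                        area = 1000 - 200 * c(4.6, 4.4, 3.9, 3.4))
  rm_ <- fit_range_model(pts)
  expect_equal(rm_$slope, -200, tolerance = 1e-10)
  expect_equal(rm_$intercept, 1000, tolerance = 1e-9)
  # round trip through inverse prediction is the identity
  expect_equal(predict_distance(rm_, pts$area), pts$d_end,
               tolerance = 1e-10)
  # prediction is strictly monotone in the area
  a <- seq(0, 500, by = 50)
  expect_true(all(diff(predict_distance(rm_, a)) < 0))
  expect_error(fit_range_model(pts[1:2, ]), "at least 3")
  expect_error(fit_range_model(tibble::tibble(d_end = rep(4, 3),
                                              area = 1:3)), "variance")
  # handle points fall outside the fit window
  with_handle <- dplyr::bind_rows(pts, tibble::tibble(d_end = c(2.9, 2.4),
                                                      area = c(0, 0)))
  expect_equal(nrow(fit_range_model(with_handle)$data), 4L)
})

test_that("synthetic campaign areas fall with distance to the phantom end", {
  d <- detect_campaign(simulate_campaign("validation", seed = 4),
                       layer = "Raw")
  rm_ <- fit_range_model(
    dplyr::transmute(d, d_end = d_end, area = silicon_area))
  expect_lt(rm_$slope, 0)
  expect_gt(glance(rm_)$r.squared, 0.9)
  # inverse predictions land within a few millimetres of the truth
  used <- rm_$data
  pred <- predict_distance(rm_, used$area)
  expect_lt(rmse_mm(pred, used$d_end), 3)
})

test_that("RMSE reproduces the published values from the printed table", {
  tab <- published_range_predictions()
  main_none <- tab[tab$campaign == "main" & tab$suppression == "none", ]
  expect_equal(round(rmse_mm(main_none$predicted_cm,
                             main_none$expected_cm), 2), 0.83)
  val_none <- tab[tab$campaign == "validation" & tab$suppression == "none", ]
  expect_lt(abs(rmse_mm(val_none$predicted_cm, val_none$expected_cm) - 1.63),
            0.03)
  expect_equal(rmse_mm(c(1, 2, 3), c(1, 2, 3)), 0)
  # permutation invariance and cm -> mm scaling
  p <- c(4.64, 4.34, 3.78, 3.49); e <- c(4.6, 4.4, 3.9, 3.4)
  o <- order(c(3, 1, 4, 2))
  expect_equal(rmse_mm(p[o], e[o]), rmse_mm(p, e))
  expect_equal(rmse_mm(p, e), 10 * sqrt(mean((p - e)^2)))
  expect_error(rmse_mm(1:3, 1:2), "paired")
})

test_that("inter-campaign relative error uses the symmetric convention", {
  a <- c(100, 200, 300)
  expect_equal(inter_campaign_relative_error(a, a), 0)
  expect_equal(inter_campaign_relative_error(a, 1.02 * a),
               mean(0.02 * a / (1.01 * a)) * 100)
  expect_lt(abs(inter_campaign_relative_error(a, 1.02 * a) - 2), 0.05)
  # reference convention divides by the first campaign
  expect_equal(inter_campaign_relative_error(a, 1.02 * a,
                                             reference = "first"), 2)
  # data-frame inputs join on beam energy
  da <- tibble::tibble(beam_energy = c(108.88, 112.25), area = c(10, 20))
  db <- tibble::tibble(beam_energy = c(112.25, 108.88), area = c(22, 10))
  expect_equal(inter_campaign_relative_error(da, db),
               mean(c(0, 2 / 21)) * 100)
  expect_error(inter_campaign_relative_error(
    da, tibble::tibble(beam_energy = 1, area = 1)), "matched")
})

test_that("matched synthetic campaigns agree within the noise expectation", {
  dm <- detect_campaign(simulate_campaign("main", seed = 4), layer = "Raw")
  dv <- detect_campaign(simulate_campaign("validation", seed = 4),
                        layer = "Raw")
  in_fit <- function(d) dplyr::filter(
    d, d_end < 4.6, d_end >= 3.4, target_region == "ERB") |>
    dplyr::transmute(beam_energy, area = silicon_area)
  err <- inter_campaign_relative_error(in_fit(dm), in_fit(dv))
  expect_gt(err, 0)
  expect_lt(err, 30)
})
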