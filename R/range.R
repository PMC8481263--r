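#' Area of the fitted silicon peak
#'
#' Analytic area of the 1.78 MeV Cauchy-Lorentz component,
#' `amplitude * scale * pi` (the full-line integral of
#' `A s^2 / ((E - m)^2 + s^2)`), plus the exact integral restricted to the
#' fitted window for cross-checking, and the per-proton normalised area when
#' a proton count is supplied. Requires an unrestricted fit: the restricted
#' model has no silicon component.
#'
#' @param fit an unrestricted `pg_peak_fit` (from [fit_unrestricted()]).
#' @param protons delivered protons for normalisation, or `NULL`.
#' @return one-row tibble with `area`, `area_window`, `area_per_proton`,
#'   `amplitude`, `mean`, `scale`.
#' @export
silicon_peak_area <- function(fit, protons = NULL) {
  stopifnot(inherits(fit, "pg_peak_fit"))
  if (fit$model != "unrestricted" ||
      !"silicon" %in% fit$components$term)
    abort("silicon_peak_area() needs an unrestricted fit with a silicon component")
  comp <- fit$components[fit$components$term == "silicon", ]
  a <- comp$amplitude
  m <- comp$mean
  s <- comp$scale
  area <- a * s * pi
  win <- fit$window
  area_window <- a * s * (atan((win[2] - m) / s) - atan((win[1] - m) / s))
  tibble::tibble(area = area, area_window = area_window,
                 area_per_proton = if (is.null(protons)) NA_real_
                                   else area / protons,
                 amplitude = a, mean = m, scale = s)
}

#' Fit the linear peak-area-to-distance model
#'
#' Ordinary least squares of silicon peak area on `d_end`, restricted to the
#' window between the inflated balloon surface and the handle
#' (3.4-4.6 cm), where the area grows linearly as the beam penetrates
#' deeper into the ERB (so the slope in `d_end` is negative). Handle-region
#' points fall outside the window and are excluded automatically.
#'
#' @param data data frame with columns `d_end` (cm) and `area`.
#' @param window `d_end` interval (cm) used for the fit, endpoints included.
#' @return object of class `pg_range_model` wrapping the `lm` fit.
#' @export
fit_range_model <- function(data, window = c(3.4, 4.6)) {
  used <- data |>
    dplyr::filter(.data$d_end >= window[1], .data$d_end <= window[2])
  if (nrow(used) < 3) abort("need at least 3 points inside the fit window")
  if (sd(used$d_end) == 0) abort("zero variance in d_end")
  fit <- lm(area ~ d_end, data = used)
  structure(list(fit = fit, window = window,
                 data = tibble::as_tibble(used),
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2])),
            class = "pg_range_model")
}

#' @export
print.pg_range_model <- function(x, ...) {
  cat(sprintf(
    "<pg_range_model> area = %.4g %+.4g * d_end on [%g, %g] cm (%d points)\n",
    x$intercept, x$slope, x$window[1], x$window[2], nrow(x$data)))
  invisible(x)
}

#' @describeIn fit_range_model coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x a `pg_range_model`.
#' @param ... unused.
#' @export
tidy.pg_range_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' @describeIn fit_range_model one-row model summary with `r.squared`,
#'   `sigma`, `n`, `slope`, `intercept`.
#' @export
glance.pg_range_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, sigma = sm$sigma,
                 n = nrow(x$data), slope = x$slope, intercept = x$intercept)
}

#' Predict the Bragg-peak distance from a measured peak area
#'
#' Inverse regression of the forward calibration line:
#' `d = (area - intercept) / slope`. For points lying exactly on the fitted
#' line this is the exact inverse (round-trip identity).
#'
#' @param model a [fit_range_model()].
#' @param area measured peak area(s).
#' @return predicted `d_end` in cm, vectorised.
#' @export
predict_distance <- function(model, area) {
  stopifnot(inherits(model, "pg_range_model"))
  if (model$slope == 0) abort("cannot invert a zero-slope range model")
  (area - model$intercept) / model$slope
}

#' Root mean square error of predicted distances, in millimetres
#'
#' @param predicted,expected paired distance vectors in cm, equal length.
#' @return RMSE in mm.
#' @examples
#' d <- published_range_predictions()
#' with(subset(d, campaign == "main" & suppression == "none"),
#'      rmse_mm(predicted_cm, expected_cm))
#' @export
rmse_mm <- function(predicted, expected) {
  if (length(predicted) != length(expected) || length(predicted) < 1)
    abort("`predicted` and `expected` must be paired and non-empty")
  sqrt(mean((predicted - expected)^2)) * 10
}

#' Mean relative error of peak areas between two campaigns
#'
#' Reproducibility measure between matched measurements of two campaigns:
#' the mean over matched energies of `|a - b|` divided by either the
#' pairwise mean `(a + b) / 2` (default) or the first campaign's value,
#' in percent.
#'
#' @param areas_a,areas_b either numeric vectors already matched by
#'   position, or data frames with `beam_energy` and `area` columns to be
#'   matched by energy.
#' @param reference `"pairwise"` (symmetric denominator) or `"first"`.
#' @return mean relative error in percent.
#' @export
inter_campaign_relative_error <- function(areas_a, areas_b,
                                          reference = c("pairwise",
                                                        "first")) {
  reference <- match.arg(reference)
  if (is.data.frame(areas_a) && is.data.frame(areas_b)) {
    j <- dplyr::inner_join(
      areas_a |> dplyr::select("beam_energy", a = "area"),
      areas_b |> dplyr::select("beam_energy", b = "area"),
      by = "beam_energy")
    if (nrow(j) == 0) abort("no matched energies between the campaigns")
    a <- j$a
    b <- j$b
  } else {
    if (length(areas_a) != length(areas_b) || length(areas_a) == 0)
      abort("area vectors must be paired and non-empty")
    a <- areas_a
    b <- areas_b
  }
  denom <- if (reference == "pairwise") (a + b) / 2 else a
  mean(abs(a - b) / denom) * 100
}
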