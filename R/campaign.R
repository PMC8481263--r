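#' Measurement campaign table
#'
#' The 43 single-spot measurements of the study: a main campaign of 23 beam
#' energies spanning 86.72-134.06 MeV through a silicon-loaded endorectal
#' balloon (ERB), plus a 10-energy campaign acquired twice -- once with the
#' ERB filled with water only ("reference") and once with the
#' silicon-dioxide/water mixture ("validation"). `d_end` is the distance
#' (cm) from the Bragg peak to the distal end of the phantom; it decreases
#' strictly with beam energy. `target_region` names the structure the spot
#' stops in: prostate, rectal wall (RW), ERB, or the balloon's silicon-free
#' handle.
#'
#' @param distinct if `TRUE`, return one row per beam energy (24 rows) with
#'   `in_main`/`in_refval` flags instead of one row per measurement (43).
#' @return A tibble with columns `beam_energy` (MeV), `d_end` (cm),
#'   `target_region`, and either `campaign` + `silicon_fill` (measurement
#'   form) or `in_main` + `in_refval` (distinct form).
#' @examples
#' campaign_table() |> dplyr::count(campaign)
#' @export
campaign_table <- function(distinct = FALSE) {
  energies <- tibble::tribble(
    ~beam_energy, ~d_end, ~target_region, ~in_main, ~in_refval,
    86.72, 7.4, "prostate", TRUE, FALSE,
    90.70, 6.9, "prostate", TRUE, FALSE,
    94.54, 6.4, "prostate", TRUE, FALSE,
    96.05, 6.2, "prostate", TRUE, FALSE,
    97.53, 6.0, "prostate", TRUE, FALSE,
    98.27, 5.9, "prostate", FALSE, TRUE,
    99.01, 5.8, "prostate", TRUE, FALSE,
    100.46, 5.6, "prostate", TRUE, FALSE,
    101.18, 5.4, "RW", TRUE, TRUE,
    103.32, 5.2, "RW", TRUE, TRUE,
    104.03, 5.1, "RW", TRUE, FALSE,
    104.73, 5.0, "RW", TRUE, TRUE,
    105.43, 4.9, "ERB", TRUE, TRUE,
    106.12, 4.8, "ERB", TRUE, TRUE,
    107.51, 4.6, "ERB", TRUE, TRUE,
    108.88, 4.4, "ERB", TRUE, TRUE,
    112.25, 3.9, "ERB", TRUE, TRUE,
    115.55, 3.4, "ERB", TRUE, TRUE,
    118.78, 2.9, "handle", TRUE, FALSE,
    121.95, 2.4, "handle", TRUE, FALSE,
    125.06, 1.9, "ERB", TRUE, FALSE,
    128.11, 1.4, "ERB", TRUE, FALSE,
    131.11, 0.9, "RW", TRUE, FALSE,
    134.06, 0.4, "RW", TRUE, FALSE
  )
  if (distinct) return(energies)
  runs <- dplyr::bind_rows(
    energies |> dplyr::filter(.data$in_main) |>
      dplyr::mutate(campaign = "main", silicon_fill = TRUE),
    energies |> dplyr::filter(.data$in_refval) |>
      dplyr::mutate(campaign = "reference", silicon_fill = FALSE),
    energies |> dplyr::filter(.data$in_refval) |>
      dplyr::mutate(campaign = "validation", silicon_fill = TRUE)
  )
  runs |>
    dplyr::select("campaign", "beam_energy", "d_end", "target_region",
                  "silicon_fill") |>
    dplyr::arrange(factor(.data$campaign,
                          c("main", "reference", "validation")),
                   .data$beam_energy)
}

#' Published linear-model range predictions
#'
#' The predicted Bragg-peak distances (cm) obtained by the study when the
#' linear peak-area model fitted over 3.4-4.6 cm was applied back to the
#' measured peak areas, next to the expected (planned) distances. Four
#' variants: main/validation campaign, each with and without BGO
#' anticoincidence background suppression.
#'
#' @return A tibble with `expected_cm`, `predicted_cm`, `campaign`
#'   (`"main"`/`"validation"`) and `suppression` (`"none"`/`"bgo"`).
#' @examples
#' d <- published_range_predictions()
#' with(subset(d, campaign == "main" & suppression == "none"),
#'      rmse_mm(predicted_cm, expected_cm))
#' @export
published_range_predictions <- function() {
  expected <- c(4.60, 4.40, 3.90, 3.40)
  tibble::tibble(
    expected_cm = rep(expected, 4),
    predicted_cm = c(4.64, 4.34, 3.78, 3.49,   # main, no suppression
                     4.73, 4.44, 3.65, 3.55,   # validation, no suppression
                     4.66, 4.35, 3.87, 3.59,   # main, BGO AC
                     4.72, 4.36, 3.63, 3.46),  # validation, BGO AC
    campaign = rep(c("main", "validation", "main", "validation"),
                   each = 4L),
    suppression = rep(c("none", "none", "bgo", "bgo"), each = 4L)
  )
}

#' Phantom and balloon geometry
#'
#' Geometry constants of the prostate phantom and inflated ERB that shape
#' the silicon signal: the beam first reaches the silicon mixture at
#' `erb_entry_dend` (the inflated balloon surface, 4.6 cm from the phantom
#' end), the signal ramp saturates at `ramp_full_dend` (the handle side of
#' the probed region, 3.4 cm), and the silicon-free handle occupies
#' `handle_interval` in `d_end`.
#'
#' @param erb_diameter inflated balloon diameter, cm.
#' @param gap rectum-wall-to-prostate gap, cm.
#' @param erb_entry_dend `d_end` at which the beam first reaches silicon, cm.
#' @param ramp_full_dend `d_end` at which the signal ramp reaches its
#'   maximum, cm.
#' @param handle_interval `d_end` interval (cm) occupied by the silicon-free
#'   handle.
#' @return An object of class `pg_geometry`.
#' @export
phantom_geometry <- function(erb_diameter = 4, gap = 0.4,
                             erb_entry_dend = 4.6, ramp_full_dend = 3.4,
                             handle_interval = c(2.4, 2.9)) {
  stopifnot(erb_entry_dend > ramp_full_dend,
            length(handle_interval) == 2L,
            handle_interval[1] <= handle_interval[2])
  tab <- campaign_table(distinct = TRUE)
  erb_range <- range(tab$d_end[tab$target_region == "ERB"])
  if (erb_entry_dend < erb_range[1] || erb_entry_dend > erb_range[2])
    abort("`erb_entry_dend` must lie inside the ERB region of the campaign table.")
  structure(list(erb_diameter = erb_diameter, gap = gap,
                 erb_entry_dend = erb_entry_dend,
                 ramp_full_dend = ramp_full_dend,
                 handle_interval = handle_interval),
            class = "pg_geometry")
}

#' Silicon line strength for a measurement
#'
#' Dimensionless intensity of the 1.78 MeV silicon de-excitation line as a
#' function of how far the spot penetrates the ERB. Spots stopping in the
#' prostate or rectal wall never reach the silicon mixture and emit nothing;
#' from the balloon surface (`erb_entry_dend`, strength 0) the strength
#' rises linearly to 1 at `ramp_full_dend` and stays saturated deeper in the
#' balloon, except inside the silicon-free handle where it drops back to 0.
#' Deterministic, vectorised over runs.
#'
#' @param d_end distance from Bragg peak to phantom end, cm.
#' @param target_region character vector, one of `"prostate"`, `"RW"`,
#'   `"ERB"`, `"handle"`.
#' @param geometry a [phantom_geometry()].
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' silicon_signal_strength(c(5.4, 4.6, 4.0, 3.4, 2.9),
#'                         c("RW", "ERB", "ERB", "ERB", "handle"))
#' @export
silicon_signal_strength <- function(d_end, target_region,
                                    geometry = phantom_geometry()) {
  stopifnot(length(d_end) == length(target_region))
  ramp <- (geometry$erb_entry_dend - d_end) /
    (geometry$erb_entry_dend - geometry$ramp_full_dend)
  s <- pmin(pmax(ramp, 0), 1)
  s[target_region %in% c("prostate", "RW")] <- 0
  in_handle <- target_region == "handle" |
    (d_end >= geometry$handle_interval[1] &
       d_end <= geometry$handle_interval[2])
  s[in_handle] <- 0
  s
}
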