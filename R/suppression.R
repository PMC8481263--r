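#' Background-suppression configuration
#'
#' The two cuts of the measurement protocol: a 10 ns prompt time-of-flight
#' window (inclusive of both endpoints) and a BGO anticoincidence veto that
#' rejects events whose shield deposit exceeds 225 keV *and* arrives after
#' the primary signal (strictly above the cut; a deposit exactly at 225 keV
#' is retained).
#'
#' @param tof_window_ns prompt window `c(lo, hi)` in ns.
#' @param ac_cut_kev shield energy cut in keV.
#' @return list of class `pg_suppression_config`.
#' @export
suppression_config <- function(tof_window_ns = c(0, 10), ac_cut_kev = 225) {
  stopifnot(length(tof_window_ns) == 2, diff(tof_window_ns) > 0,
            ac_cut_kev > 0)
  structure(list(tof_window_ns = tof_window_ns, ac_cut_kev = ac_cut_kev),
            class = "pg_suppression_config")
}

#' Time-of-flight cut
#'
#' Keeps events whose time of flight lies inside the prompt window
#' (endpoints included).
#'
#' @param events tibble with a `tof_ns` column.
#' @param config a [suppression_config()].
#' @return the prompt subset of `events`.
#' @export
apply_tof_cut <- function(events, config = suppression_config()) {
  if (is.null(events[["tof_ns"]])) abort("`events` must have a `tof_ns` column")
  events[events$tof_ns >= config$tof_window_ns[1] &
           events$tof_ns <= config$tof_window_ns[2], , drop = FALSE]
}

#' BGO anticoincidence cut
#'
#' Rejects events whose companion-shield deposit is strictly above the
#' energy cut and arrived after the primary signal; everything else is
#' retained.
#'
#' @param events tibble with `ac_energy_kev` and `ac_after_primary` columns.
#' @param config a [suppression_config()].
#' @return the surviving subset of `events`.
#' @export
apply_ac_cut <- function(events, config = suppression_config()) {
  if (is.null(events[["ac_energy_kev"]]) || is.null(events[["ac_after_primary"]]))
    abort("`events` must have `ac_energy_kev` and `ac_after_primary` columns")
  events[!(events$ac_energy_kev > config$ac_cut_kev &
             events$ac_after_primary), , drop = FALSE]
}

#' Build the four suppression layers from an event stream
#'
#' `Raw` is the untouched stream, `TOF` the prompt-window subset, `BGO` the
#' anticoincidence survivors, and `All` the events surviving both cuts, so
#' `All` is exactly the intersection of `TOF` and `BGO`.
#'
#' @param events event tibble (see [simulate_event_stream()]).
#' @param config a [suppression_config()].
#' @return named list of event tibbles `Raw`, `TOF`, `BGO`, `All`.
#' @export
build_layers <- function(events, config = suppression_config()) {
  tof <- apply_tof_cut(events, config)
  bgo <- apply_ac_cut(events, config)
  list(Raw = events, TOF = tof, BGO = bgo,
       All = apply_ac_cut(tof, config))
}
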