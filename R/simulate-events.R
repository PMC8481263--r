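#' Exponentially modified Gaussian pulse shape
#'
#' Density-normalised EMG (Gaussian of width `sigma` convolved with an
#' exponential of decay `tau`), scaled by `area`, so the integral over the
#' real line equals `area`.
#'
#' @param x sample positions.
#' @param mu Gaussian location.
#' @param sigma Gaussian width (> 0).
#' @param tau exponential decay constant (> 0).
#' @param area pulse integral.
#' @return numeric vector of pulse amplitudes.
#' @export
emg <- function(x, mu, sigma, tau, area = 1) {
  stopifnot(sigma > 0, tau > 0)
  u <- (mu + sigma^2 / tau - x) / (sigma * sqrt(2))
  # erfc(u) = 2 * pnorm(-u * sqrt(2)); computed on the log scale for
  # numerical stability in the far tail
  log_erfc <- pnorm(-u * sqrt(2), log.p = TRUE) + log(2)
  area * exp(log(1 / (2 * tau)) +
               (sigma^2 / (2 * tau^2)) - (x - mu) / tau + log_erfc)
}

# position of the EMG maximum relative to mu (depends on sigma, tau only)
emg_mode_shift <- function(sigma, tau) {
  optimize(function(d) emg(d, 0, sigma, tau), c(-4 * sigma, 6 * (sigma + tau)),
           maximum = TRUE)$maximum
}

#' Simulate a detector trace of up to three EMG pulses
#'
#' Builds a sampled trace as a sum of EMG pulses plus white Gaussian noise,
#' with optional digitizer overflow clipping. Ground truth (area, mode,
#' height per pulse, plus pile-up and overflow flags) is returned alongside
#' so trace-processing can be validated against it. Pulses are specified by
#' their integral `area` and the sample index `mode` of their maximum; the
#' Gaussian location is placed so the realised maximum falls at `mode`.
#'
#' @param pulses data frame with columns `area` and `mode`, optionally
#'   `sigma` and `tau` (samples); at most 3 rows.
#' @param noise_sd white-noise standard deviation.
#' @param length trace length in samples.
#' @param seed integer seed.
#' @param clip_max digitizer saturation level; samples above it are clipped
#'   and the overflow flag is set. `NULL` disables clipping.
#' @param pileup_separation mode separation (samples) below which two pulses
#'   are flagged as pile-up; default 2 x the Gaussian width.
#' @return A list of class `pg_trace`: `trace` (numeric), `truth` (tibble
#'   with `area`, `mode`, `height`, `sigma`, `tau`), `overflow`, `pileup`.
#' @examples
#' tr <- simulate_trace(data.frame(area = 500, mode = 40), noise_sd = 0)
#' max(tr$trace) - tr$truth$height
#' @export
simulate_trace <- function(pulses, noise_sd = 1, length = 192, seed = NULL,
                           clip_max = NULL, pileup_separation = NULL) {
  pulses <- as.data.frame(pulses)
  if (nrow(pulses) > 3)
    abort("at most 3 pulses per trace are supported")
  if (!is.null(pulses$mode) && nrow(pulses) > 0 &&
      (any(pulses$mode < 1) || any(pulses$mode > length)))
    abort("pulse modes must lie within the trace")
  if (is.null(pulses$sigma)) pulses$sigma <- rep(4, nrow(pulses))
  if (is.null(pulses$tau)) pulses$tau <- rep(8, nrow(pulses))
  x <- seq_len(length)
  trace <- numeric(length)
  truth <- tibble::tibble(area = numeric(0), mode = numeric(0),
                          height = numeric(0), sigma = numeric(0),
                          tau = numeric(0))
  for (i in seq_len(nrow(pulses))) {
    shift <- emg_mode_shift(pulses$sigma[i], pulses$tau[i])
    mu <- pulses$mode[i] - shift
    trace <- trace + emg(x, mu, pulses$sigma[i], pulses$tau[i],
                         pulses$area[i])
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      area = pulses$area[i], mode = pulses$mode[i],
      height = emg(pulses$mode[i], mu, pulses$sigma[i], pulses$tau[i],
                   pulses$area[i]),
      sigma = pulses$sigma[i], tau = pulses$tau[i]
    ))
  }
  if (noise_sd > 0)
    trace <- trace + with_seed_(seed, rnorm(length, 0, noise_sd))
  overflow <- FALSE
  if (!is.null(clip_max) && any(trace > clip_max)) {
    trace <- pmin(trace, clip_max)
    overflow <- TRUE
  }
  if (is.null(pileup_separation) && nrow(truth) > 0)
    pileup_separation <- 2 * mean(truth$sigma)
  pileup <- nrow(truth) > 1 &&
    min(diff(sort(truth$mode))) < pileup_separation
  structure(list(trace = trace, truth = truth, overflow = overflow,
                 pileup = pileup),
            class = "pg_trace")
}

#' Simulate a time-of-flight / anticoincidence event stream
#'
#' Draws labelled events the suppression cuts can act on. Prompt gammas
#' arrive inside the prompt time-of-flight window; uncorrelated background
#' (for example neutron-capture gammas) arrives uniformly over the spill
#' micro-period, so a fraction of it leaks into the window. Each event also
#' carries a companion (BGO shield) deposit that may veto it, with
#' different survival probabilities for prompt and background events, and an
#' absolute timestamp inside the declared spill structure. The defaults
#' reproduce the study's cut bookkeeping: the TOF cut keeps 13% of events,
#' the shield veto keeps 32%, and both together keep 6%.
#'
#' @param n_events number of events.
#' @param prompt_fraction fraction of events that are true prompt gammas.
#' @param spill_ns spill micro-period (ns) over which background arrival
#'   times are uniform.
#' @param tof_window prompt window in ns, `c(lo, hi)`.
#' @param ac_survival_prompt,ac_survival_background probability that a
#'   prompt/background event survives the shield veto (no qualifying
#'   deposit above the cut arriving after the primary).
#' @param ac_cut_kev shield energy cut, keV.
#' @param spill_structure tibble of macroscopic spill intervals (`start`,
#'   `end`, ms) over which event timestamps are spread; default 14 spills.
#' @param seed integer seed.
#' @return tibble with `event_id`, `tof_ns`, `energy_mev`, `ac_energy_kev`,
#'   `ac_after_primary`, `time_ms`, and ground-truth label `is_prompt`.
#' @export
simulate_event_stream <- function(n_events,
                                  prompt_fraction = 0.072,
                                  spill_ns = 160,
                                  tof_window = c(0, 10),
                                  ac_survival_prompt = 0.593,
                                  ac_survival_background = 0.299,
                                  ac_cut_kev = 225,
                                  spill_structure = default_spills(),
                                  seed = NULL) {
  stopifnot(n_events >= 0, prompt_fraction >= 0, prompt_fraction <= 1,
            spill_ns >= diff(tof_window))
  if (n_events == 0)
    return(tibble::tibble(event_id = integer(0), tof_ns = numeric(0),
                          energy_mev = numeric(0),
                          ac_energy_kev = numeric(0),
                          ac_after_primary = logical(0),
                          time_ms = numeric(0), is_prompt = logical(0)))
  with_seed_(seed, {
    is_prompt <- runif(n_events) < prompt_fraction
    tof <- ifelse(is_prompt,
                  runif(n_events, tof_window[1], tof_window[2]),
                  runif(n_events, tof_window[1], tof_window[1] + spill_ns))
    survives <- runif(n_events) <
      ifelse(is_prompt, ac_survival_prompt, ac_survival_background)
    # survivors: deposit below the cut, or a large deposit arriving BEFORE
    # the primary (which the ordering convention retains)
    early_big <- survives & runif(n_events) < 0.2
    ac_energy <- ifelse(survives,
                        ifelse(early_big,
                               runif(n_events, ac_cut_kev, 4 * ac_cut_kev),
                               runif(n_events, 0, ac_cut_kev)),
                        runif(n_events, ac_cut_kev, 8 * ac_cut_kev))
    ac_after <- ifelse(survives, !early_big, TRUE)
    spill_idx <- sample.int(nrow(spill_structure), n_events, replace = TRUE)
    time_ms <- runif(n_events, spill_structure$start[spill_idx],
                     spill_structure$end[spill_idx])
    tibble::tibble(event_id = seq_len(n_events), tof_ns = tof,
                   energy_mev = runif(n_events, 0, 8.192),
                   ac_energy_kev = ac_energy, ac_after_primary = ac_after,
                   time_ms = time_ms, is_prompt = is_prompt)
  })
}

#' Default synchrotron spill structure
#'
#' 14 spills as in the measurement protocol: a few seconds of beam
#' separated by pauses.
#'
#' @param n_spills number of spills.
#' @param spill_ms spill duration, ms.
#' @param pause_ms pause between spills, ms.
#' @return tibble with `start` and `end` (ms).
#' @export
default_spills <- function(n_spills = 14, spill_ms = 2000, pause_ms = 2800) {
  start <- (seq_len(n_spills) - 1) * (spill_ms + pause_ms)
  tibble::tibble(start = start, end = start + spill_ms)
}
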