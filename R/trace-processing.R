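#' Fit EMG pulses to a detector trace
#'
#' Locates up to `max_peaks` pulse candidates and fits a sum of
#' exponentially modified Gaussians by nonlinear least squares, reporting
#' the derived triple the downstream analysis uses -- pulse integral
#' (`area`), sample index of the maximum (`mode`) and amplitude at the
#' maximum (`height`) -- together with the trace's adjusted R-squared.
#' Overflow (clipped plateau at the digitizer maximum) and pile-up
#' (fitted modes closer than `pileup_separation`) are flagged; a
#' non-convergent fit is returned flagged `discarded` rather than raised.
#'
#' @param trace numeric trace or a [simulate_trace()] result.
#' @param max_peaks maximum number of pulses to fit (3).
#' @param pileup_separation mode separation (samples) below which pulses are
#'   flagged as pile-up; default 2 x the fitted Gaussian width.
#' @param clip_max digitizer saturation level used for overflow detection;
#'   default the trace maximum if at least two samples sit exactly there.
#' @param min_height peak candidates below this amplitude are ignored;
#'   default 5% of the trace maximum.
#' @return tibble with one row per fitted pulse: `area`, `mode`, `height`,
#'   `sigma`, `tau`, `r2_adjusted`, `overflow`, `pileup`, `discarded`.
#' @export
fit_pulses <- function(trace, max_peaks = 3, pileup_separation = NULL,
                       clip_max = NULL, min_height = NULL) {
  if (inherits(trace, "pg_trace")) trace <- trace$trace
  trace <- as.numeric(trace)
  if (length(trace) < 8) abort("trace too short to fit")
  x <- seq_along(trace)

  # overflow: a plateau of >= 2 samples at the digitizer ceiling
  if (is.null(clip_max)) {
    top <- max(trace)
    overflow <- sum(abs(trace - top) < 1e-9 * max(abs(top), 1)) >= 2
  } else {
    overflow <- any(trace >= clip_max * (1 - 1e-9))
  }

  if (is.null(min_height)) min_height <- 0.05 * max(trace)
  # local maxima on a lightly smoothed copy, tallest first
  sm <- stats::filter(trace, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- trace[is.na(sm)]
  cand <- which(diff(sign(diff(sm))) == -2) + 1L
  cand <- cand[sm[cand] >= min_height]
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  # enforce a minimal spacing so one wide pulse yields one candidate
  keep <- integer(0)
  for (p in cand) if (all(abs(p - keep) > 6)) keep <- c(keep, p)
  keep <- head(sort(keep), max_peaks)

  empty <- tibble::tibble(area = numeric(0), mode = numeric(0),
                          height = numeric(0), sigma = numeric(0),
                          tau = numeric(0), r2_adjusted = numeric(0),
                          overflow = logical(0), pileup = logical(0),
                          discarded = logical(0))
  if (length(keep) == 0) return(empty)

  k <- length(keep)
  par0 <- c(rbind(pmax(trace[keep], min_height) * 25, keep, rep(4, k),
                  rep(8, k)))
  names(par0) <- paste0(rep(c("A", "mu", "sigma", "tau"), k),
                        rep(seq_len(k), each = 4))
  model_fun <- function(par) {
    f <- numeric(length(x))
    for (j in seq_len(k)) {
      A <- par[4 * j - 3]; mu <- par[4 * j - 2]
      s <- max(par[4 * j - 1], 0.3); tau <- max(par[4 * j], 0.3)
      f <- f + emg(x, mu, s, tau, A)
    }
    f
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = function(p) trace - model_fun(p),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL
  )
  discarded <- is.null(fit) || fit$info %in% c(0, 5)
  par <- if (is.null(fit)) par0 else fit$par

  rows <- purrr::map_dfr(seq_len(k), function(j) {
    A <- unname(par[4 * j - 3]); mu <- unname(par[4 * j - 2])
    s <- max(unname(par[4 * j - 1]), 0.3)
    tau <- max(unname(par[4 * j]), 0.3)
    shift <- emg_mode_shift(s, tau)
    tibble::tibble(area = A, mode = mu + shift,
                   height = emg(mu + shift, mu, s, tau, A),
                   sigma = s, tau = tau)
  })
  resid <- trace - model_fun(par)
  ss_tot <- sum((trace - mean(trace))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  n <- length(trace); p <- 4 * k
  r2_adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else r2

  if (is.null(pileup_separation)) pileup_separation <- 2 * mean(rows$sigma)
  pileup <- k > 1 && min(diff(sort(rows$mode))) < pileup_separation
  rows |>
    dplyr::mutate(r2_adjusted = r2_adj, overflow = overflow,
                  pileup = pileup, discarded = discarded)
}

#' Adjusted-R-squared event filter
#'
#' The per-run quality cut on trace fits: events whose adjusted R-squared
#' falls below `mean - sigma_multiplier * sd` of the run's distribution are
#' rejected. With the default multiplier of 7.5 essentially all regular
#' events survive and only catastrophic fit failures are removed. If all
#' values are identical the standard deviation is zero, the threshold equals
#' the mean, and every event is accepted.
#'
#' @param fits data frame with an `r2_adjusted` column (one row per event),
#'   e.g. stacked [fit_pulses()] output.
#' @param sigma_multiplier the number of standard deviations below the mean.
#' @return list with `accepted` (the surviving rows) and `threshold`.
#' @examples
#' r2_threshold_filter(data.frame(r2_adjusted = c(0.99, 0.98, 0.99, 0.10)))
#' @export
r2_threshold_filter <- function(fits, sigma_multiplier = 7.5) {
  r2 <- fits[["r2_adjusted"]]
  if (is.null(r2)) abort("`fits` must have an `r2_adjusted` column")
  finite <- is.finite(r2)
  if (sum(finite) < 2)
    abort("need at least 2 finite adjusted R-squared values")
  mu <- mean(r2[finite])
  sdev <- sd(r2[finite])
  threshold <- mu - sigma_multiplier * sdev
  list(accepted = fits[finite & r2 >= threshold, , drop = FALSE],
       threshold = threshold)
}

#' Keep only in-spill events
#'
#' @param events tibble with a `time_ms` column.
#' @param spill_structure tibble of spill intervals (`start`, `end`, ms);
#'   events with `start <= time_ms <= end` for any interval are kept.
#' @return the in-spill subset of `events`.
#' @export
select_in_spill <- function(events, spill_structure) {
  if (is.null(events[["time_ms"]])) abort("`events` must have a `time_ms` column")
  if (is.null(spill_structure) || nrow(spill_structure) == 0)
    abort("no spill intervals declared")
  idx <- findInterval(events$time_ms, spill_structure$start)
  keep <- idx >= 1 & events$time_ms <= spill_structure$end[pmax(idx, 1)]
  events[keep, , drop = FALSE]
}

#' Non-paralyzable dead-time correction
#'
#' Live-time scaling `observed / (1 - dead_time_fraction)` under the
#' non-paralyzable detector model. When an event rate `rate` (per second)
#' and per-event dead time `tau` (seconds) are supplied instead, the rate
#' form `m = n / (1 - n * tau)` is used.
#'
#' @param observed_counts observed counts (vectorised).
#' @param dead_time_fraction measured dead-time fraction in `[0, 1)`; the
#'   measurements stayed below 15%, so larger values trigger a warning.
#' @param rate,tau optional event rate and per-event dead time for the rate
#'   form (both must be given; `dead_time_fraction` is then ignored).
#' @return corrected counts, always `>= observed_counts`.
#' @examples
#' correct_dead_time(850000, 0.15)
#' @export
correct_dead_time <- function(observed_counts, dead_time_fraction = NULL,
                              rate = NULL, tau = NULL) {
  if (!is.null(rate) || !is.null(tau)) {
    if (is.null(rate) || is.null(tau))
      abort("the rate form needs both `rate` and `tau`")
    if (any(rate * tau >= 1)) abort("rate * tau must be < 1")
    return(observed_counts / (1 - rate * tau))
  }
  if (is.null(dead_time_fraction))
    abort("supply `dead_time_fraction`, or `rate` and `tau`")
  if (any(dead_time_fraction < 0) || any(dead_time_fraction >= 1))
    abort("`dead_time_fraction` must be in [0, 1)")
  if (any(dead_time_fraction > 0.15))
    warn("dead-time fraction above 15%, outside the measured regime")
  observed_counts / (1 - dead_time_fraction)
}

#' Histogram event values onto a fixed binning
#'
#' Bins are half-open `[low, high)` -- a value exactly on an interior edge
#' goes to the right-hand bin -- and the last bin is closed. Out-of-range
#' values are dropped and counted in the `out_of_range` attribute, so
#' `sum(counts) + out_of_range == length(values)`.
#'
#' @param values pulse integrals or energies.
#' @param bin_edges strictly increasing vector of `n_bins + 1` edges.
#' @return integer vector of `n_bins` counts with attribute `out_of_range`.
#' @export
histogram_events <- function(values, bin_edges) {
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing")
  n_bins <- length(bin_edges) - 1L
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= n_bins
  counts <- tabulate(idx[in_range], nbins = n_bins)
  attr(counts, "out_of_range") <- sum(!in_range)
  counts
}
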