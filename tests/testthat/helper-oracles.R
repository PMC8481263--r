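# Independent reference implementations used as oracles in tests.

# plain-loop SNIP with LLS transform and decreasing window, written
# independently of the package's vectorised version
snip_reference <- function(y, iterations) {
  n <- length(y)
  v <- log(log(sqrt(pmax(y, 0) + 1) + 1) + 1)
  for (m in seq(min(iterations, n %/% 2), 1)) {
    w <- v
    for (i in (m + 1):(n - m)) {
      cand <- (v[i - m] + v[i + m]) / 2
      if (cand < v[i]) w[i] <- cand
    }
    v <- w
  }
  pmax(pmin((exp(exp(v) - 1) - 1)^2 - 1, y), 0)
}

# Lorentzian peak-height parameterisation used throughout the package
lorentz_shape <- function(e, amplitude, mean, scale) {
  amplitude * scale^2 / ((e - mean)^2 + scale^2)
}

# a clean analysis window: constant + oxygen line (+ optional silicon),
# Gaussian noise
make_window <- function(constant = 100, a_ox = 300, a_si = 0,
                        noise_sd = 0, seed = NULL) {
  e <- energy_axis()
  e <- e[e >= 1.58 & e < 1.84]
  y <- constant + lorentz_shape(e, a_ox, 1.635, 0.0285) +
    lorentz_shape(e, a_si, 1.78, 0.031)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(e), 0, noise_sd)
  }
  tibble::tibble(energy = e, counts = y)
}
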