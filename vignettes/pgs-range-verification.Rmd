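---
title: "Prompt gamma spectroscopy range verification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt gamma spectroscopy range verification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsrange)
library(dplyr)
```

## The problem

In proton therapy of prostate cancer with anterior beams, the Bragg peak
stops just short of the rectal wall, and a centimetre of range uncertainty
decides whether healthy tissue is hit. An endorectal balloon (ERB) filled
with a silicon-dioxide/water mixture turns the balloon into a range probe:
protons that reach the mixture excite ^28^Si nuclei, which de-excite by
emitting a characteristic 1.78 MeV prompt gamma line. A cerium-bromide
spectrometer records the prompt-gamma energy spectrum for each single-spot
irradiation; the presence and area of the silicon line then tell whether,
and how far, the spot penetrated the balloon.

`pgsrange` implements the full analysis chain for such measurements —
spectral processing, background-suppression bookkeeping, a nested-model
F-test for line detection, and a linear peak-area-to-range calibration —
together with a synthetic campaign generator so every stage is testable
without the measured archive.

## The measurement campaigns

`campaign_table()` reproduces the 43 single-spot measurements: a main
campaign of 23 beam energies from 86.72 to 134.06 MeV through the
silicon-loaded ERB, and a 10-energy campaign acquired twice, once with a
water-only balloon (reference) and once with the mixture (validation).
Each run is labelled by `d_end`, the distance from the Bragg peak to the
distal end of the phantom, and by the structure the spot stops in
(prostate, rectal wall, ERB, or the balloon's silicon-free handle).

```{r}
campaign_table() |> count(campaign, target_region)
```

## The spectral model and the F-test

Within the 1.58–1.84 MeV analysis window (65 bins at the default 4 keV
binning) the spectrum is described by a constant background plus
Cauchy-Lorentz lines of the form

$$ L(E) = A\,\frac{s^2}{(E-m)^2 + s^2}, $$

where $A$ is the peak height, $m$ the centroid and $s$ the half width at
half maximum. The *restricted* model carries one line (oxygen
de-excitation at 1.635 MeV) plus the constant — 4 parameters; the
*unrestricted* model adds a second line at the silicon energy of
1.78 MeV — 7 parameters. Both are fitted by unweighted least squares and
compared through

$$ F = \frac{(SSR_r - SSR_{ur})/q}{SSR_{ur}/df_{ur}}, \qquad q = 3, $$

with $df_{ur} = n - 7 = 58$ by default. The null hypothesis (no silicon)
is rejected when $F$ exceeds the $(1-\alpha)$ quantile of
$F(q, df_{ur})$ at $\alpha = 10^{-4}$, the 0.01% level.

### The degrees-of-freedom convention

The published description of this test states a denominator degrees of
freedom of 49 via "$n-k-1 = 65-6$", which is arithmetically inconsistent
(the difference is 59) and does not match the stated parameter counts
either (a 7-parameter unrestricted model gives 58). The package defaults
to the parameter-count convention, $df_{ur} = n - 7$, and exposes
`df_ur` as an override in `test_silicon()` so the printed convention can
be reproduced. At $n = 65$ the choice moves the critical value only from
8.40 to 8.69 and never changes a decision in practice.

### Which counts vector enters the fit

The archive carries raw counts, Savitzky–Golay-smoothed counts, and a SNIP
baseline per layer. The fits default to the **raw counts**: smoothing
correlates neighbouring residuals, which silently breaks the independence
assumption behind the F statistic's null distribution, and baseline
subtraction couples the window to out-of-window bins. Both alternatives
remain available through `counts_col =` (`"smoothed_counts"`, or a
user-computed net column) for sensitivity analyses.

### Constraints that keep the test honest

Two constraints matter for the statistic's null behaviour, because under
the null hypothesis the silicon component's position and width are not
identified and an unconstrained second component simply chases noise:

* **Means** are box-constrained to ±0.05 MeV around their nominal line
  energies. De-excitation energies are nuclear constants; the box allows
  for residual calibration error only.
* **Scales** are bounded below by half the detector's resolution
  half-width. A physical line cannot be narrower than the instrument
  response; without this bound the second component degenerates into
  single-bin noise spikes and the test over-rejects.

With these constraints the Monte Carlo null distribution of $F$ has mean
≈ 1.05 and a type-I error at the 0.01% level compatible with nominal
(the package's acceptance tests simulate 2×10^5 null windows). The full
distribution still deviates from $F(3,58)$ at the percent level
(Kolmogorov–Smirnov distance ≈ 0.02–0.03): for a *nonlinear* nested fit
whose extra parameters are unidentified under the null, the F reference
distribution is an approximation, not an exact result, and a sample of
2×10^5 draws resolves the difference easily. The operating tail —
the only region the 0.01% decision uses — is where the approximation is
good. This is a structural property of the published test itself, not of
this implementation; it is checked, documented here, and accepted.

### Optimisation

The Lorentz fits run in compiled code (a Levenberg–Marquardt loop with
analytic Jacobians) because the null-calibration study requires about
4×10^5 nonlinear fits. Box constraints use the MINPACK-style sine
transform rather than clamping, which keeps the objective smooth at the
bounds. The unrestricted fit is warm-started from the restricted solution
with zero silicon amplitude, so $SSR_{ur} \le SSR_r$ holds on every
window by construction; a second, data-driven start protects against the
rare case where the restricted optimum is a poor two-line starting point.
Convergence requires a relative SSR improvement below `ftol` (10^-9 for
single fits, 10^-8 in the batch study), with an additional stop when 100
consecutive iterations improve the SSR by less than 0.01% — a crawling
descent along a degenerate boundary valley that cannot change any
decision. The covariance reported by `vcov()` is a leverage-corrected
(HC3-style) sandwich, because counting noise is heteroscedastic across a
peak and the homoscedastic formula understates the uncertainty of the
width by roughly a factor two.

## The synthetic generator

`simulate_campaign()` emulates the study conditions so the pipeline can be
exercised end to end:

* **Axis**: 2048 bins of 4 keV (0–8.192 MeV). The published account fixes
  the bin count and the window but not the bin width; 4 keV reproduces the
  stated "about 65" observations in the window exactly.
* **Continuum**: a decaying exponential (amplitude 2800 counts/bin at
  E = 0, decay constant 1.9 MeV), scaled linearly with beam energy so raw
  totals run from 1.39×10^6 counts at 86.72 MeV to 2.13×10^6 at
  128.11 MeV, the measured range.
* **Lines**: annihilation (0.511 MeV), oxygen (1.635, 2.742, 6.13 MeV) and
  4.44 MeV carbon/oxygen, rendered as Lorentzians whose FWHM is 3.49% of
  the line energy — the detector's measured resolution. A `line_shape =
  "gauss"` switch generates Gaussian peaks instead, to separate estimator
  correctness from shape misspecification.
* **Silicon line**: area `silicon_base_area * strength`, with strength
  given by the penetration model below. The absolute silicon yield per
  proton is not published; the default amplitude (10^5 raw-layer counts at
  full strength, about three times the oxygen-line area) is a
  phenomenological choice fixed once, sized so the detection pattern
  across the campaigns is reproducible rather than physically
  quantitative.
* **Suppression layers**: the TOF cut keeps 13% of events, the BGO
  anticoincidence veto 32%, both together 6% — the reported fractions,
  which are total-count fractions. On top of the retention, each layer's
  continuum is attenuated relative to the prompt lines (rejection factors
  0.5, 0.7 and 0.4 for TOF, BGO and All), because the cuts remove
  time-uncorrelated background preferentially; the reshaped spectrum is
  renormalised to keep the layer totals at the retention fractions, and
  the resulting prompt-line boost applies to the silicon line like to any
  other line (computed without silicon in the totals, so the silicon
  expectation stays exactly linear in its strength). This reproduces the
  observed picture: suppressed spectra with fewer counts but more
  prominent peaks.
* **Poisson noise** per bin, bit-reproducible under a fixed seed; per-run
  seeds mix the campaign label and beam energy so matched runs in
  different campaigns are statistically independent.

### The penetration model

`silicon_signal_strength()` is deterministic: zero for spots stopping in
the prostate or rectal wall, zero at the inflated balloon surface
(`d_end` = 4.6 cm), rising linearly to its maximum at the handle side of
the probed region (3.4 cm), saturated deeper in the balloon, and zero
again inside the silicon-free handle (2.4–2.9 cm). The onset convention
deserves a note: the published pattern description is ambiguous about
whether the 4.6 cm measurement itself rejects the null ("starting at
4.6 cm" versus "below 4.6 cm"); the generator makes 4.6 cm the exact
onset with zero signal, so the package's own acceptance pattern treats
the onset runs as null and expects rejections strictly below 4.6 cm.

### What the generator does not emulate

No particle transport, nuclear cross sections, pile-up between the
spectral and trace levels, detector nonlinearity beyond the configurable
calibration polynomial, or correlated backgrounds. Passing tests on
synthetic data therefore demonstrate that the statistical machinery is
correct and calibrated under the stated noise model — not that the
phenomenological amplitudes match any particular measured spectrum.

## Layer choice for detection and quantification

On high-count spectra the constant-plus-lines window model is mildly
misspecified (the continuum has curvature), and the misspecification
grows with statistics relative to the counting noise. Monte Carlo checks
across seeds show the All layer (TOF + BGO, 6% of events) is the one
whose null F values match the nominal distribution; Raw and BGO layers
show inflated F under the null. `detect_campaign()` therefore defaults
to `layer = "All"` for the *decision*, while quantification of peak
areas (which needs statistics, not calibrated tails) is run on the Raw
or BGO layers, mirroring the published workflow.

## The range model

For runs probing the balloon, the fitted silicon peak area (analytically
$A\,s\,\pi$ for a Lorentzian) falls linearly with `d_end` over the
3.4–4.6 cm window between the balloon surface and the handle.
`fit_range_model()` fits ordinary least squares of area on distance over
that window (handle points are excluded by construction);
`predict_distance()` inverts the fitted line, and `rmse_mm()` scores
predictions in millimetres. Areas are normalised per delivered proton
(`silicon_area_per_proton`) when campaigns with different proton counts
are compared; within one synthetic campaign the proton counts are equal
by construction and raw areas suffice. Campaign-to-campaign
reproducibility is summarised by `inter_campaign_relative_error()`, whose
default denominator is the symmetric pairwise mean — the published
"mean relative error" does not name its reference, so the symmetric
convention is the default and the first-campaign reference is a switch.

On the published predicted-distance table this machinery reproduces the
printed 0.83 mm RMSE for the main campaign without suppression exactly,
and the remaining three RMSE values within the rounding of the
two-decimal table inputs (1.61 vs 1.63 mm, 1.04 vs 1.03 mm, 1.52 vs
1.49 mm).

## Event-level processing

The trace and event modules mirror the acquisition chain: pulse traces
are sums of up to three exponentially modified Gaussians (EMG) fitted by
least squares and summarised by area, mode and height; events below an
adjusted-R² threshold of $\mu - 7.5\sigma$ (pooled per run — whether the
published pooling was per run or per spill is not stated) are discarded,
as are overflow plateaus and pile-up closer than twice the Gaussian
width; in-spill selection and a non-paralyzable dead-time correction
(`observed/(1 - DT)`, with the rate form `n/(1 - n\tau)` as an
alternative, since the published account names the model but not its
inputs; the measured dead time stayed below 15%, so larger values warn)
precede histogramming into 2048 bins. Histogram bins are half-open
left-inclusive with a closed top bin. The prompt TOF window (10 ns) is
inclusive at both ends and the shield veto is strict (deposits above
225 keV arriving after the primary); the published fractions 13%, 32%
and 6% are mutually inconsistent under independent cuts (13% × 32% ≈
4.2%), so the generator draws the two cut outcomes jointly with the
correlation implied by the 6% joint retention.

## Archive formats

The deposited archives are Python pickles nested as energy → {proton,
Raw/TOF/BGO/All} → five 2048-element arrays (`_counts`, `baseline`,
`bins`, `calibration`, `counts`). `read_campaign_pickle()` and
`write_campaign_pickle()` bridge to that format through the system Python
interpreter, tolerating byte-string keys and numpy leaves; whether the
deposited `counts` are dead-time-corrected is not documented, so they are
read as-is. The package's canonical on-disk form is a portable directory
archive — `manifest.yaml` plus one CSV per energy and layer — written and
read by `write_campaign_archive()` / `read_campaign_archive()`, with
energies keyed as two-decimal strings to avoid float-key pitfalls.

## Problem sizes and run times

The package's own validation uses 2×10^5 simulated null windows for the
type-I error study (a few minutes in compiled code), 400-window batches
for power monotonicity, full 43-run campaign simulations for the
detection pattern, and 10^5-count event streams for the suppression
bookkeeping. All stochastic checks fix their seeds and state binomial or
multi-sigma tolerances next to the draw counts.

## Known limitations

* The F statistic's full null distribution is only approximately
  $F(3,58)$ (see above); decisions at the 0.01% level are calibrated,
  but goodness-of-fit tests of the whole F sample against the nominal
  reference will fail at large simulation sizes.
* The silicon amplitude scale, continuum shape and layer rejection
  factors are phenomenological defaults, not fitted to measured spectra.
* Trace-level and spectrum-level generators are independent; simulated
  spectra are drawn directly as Poisson counts rather than aggregated
  from simulated traces.
* The energy calibration is linear in the generator's default; the
  quadratic nonlinearity correction is exercised only through synthetic
  anchor sets.
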