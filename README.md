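# pgsrange

Prompt gamma spectroscopy (PGS) analysis for verifying single-spot proton
ranges in a prostate phantom carrying an endorectal balloon (ERB) filled
with a silicon-dioxide/water mixture.

## The problem and the method

In proton therapy of prostate cancer with anterior beams, the Bragg peak
stops millimetres short of the rectal wall. A silicon-loaded ERB acts as a
range probe: protons reaching the mixture excite ^28^Si, which emits a
characteristic 1.78 MeV prompt gamma line, recorded by a CeBr₃
spectrometer alongside the 1.635 MeV oxygen de-excitation line.

The statistical core is a nested-model comparison in the 1.58–1.84 MeV
window (n = 65 bins at 4 keV). Each de-excitation line is a Cauchy–Lorentz
peak `A·s²/((E−m)² + s²)`; the restricted model has one line (oxygen) plus
a constant (4 parameters), the unrestricted adds the silicon line
(7 parameters). Silicon is declared present when

    F = ((SSR_r − SSR_ur)/q) / (SSR_ur/df_ur),  q = 3, df_ur = n − 7 = 58

exceeds the F(q, df_ur) quantile at the 0.01% level (α = 10⁻⁴). The fitted
silicon peak area (analytically `A·s·π`) then maps linearly to `d_end`,
the distance from the Bragg peak to the phantom end, over the 3.4–4.6 cm
window between the inflated balloon surface and the balloon's silicon-free
handle; inverting that line predicts the proton range with millimetre
accuracy.

The package implements the full chain — synthetic measurement campaigns
(43 runs, 86.72–134.06 MeV, matching the published campaign table),
trace and event processing (EMG pulse fits, adjusted-R² filtering,
in-spill selection, non-paralyzable dead-time correction), spectral
processing (energy calibration, Savitzky–Golay smoothing, SNIP baseline),
background-suppression layers (10 ns TOF window, 225 keV BGO
anticoincidence veto; retentions 13%/32%/6%), silicon detection, and range
prediction — plus readers/writers for the deposited pickle archives and a
portable CSV/YAML archive format. See the methods vignette
(`vignettes/pgs-range-verification.Rmd`) for the models, conventions and
design decisions.

## Worked example

```r
library(pgsrange)

# simulate the validation campaign (silicon-filled ERB, 10 energies)
camp <- simulate_campaign("validation", seed = 7)

# F-test every measurement on the fully suppressed (All) layer
report <- detect_campaign(camp, layer = "All")
dplyr::select(report, beam_energy, d_end, target_region, f_value, reject)
#> # A tibble: 10 × 5
#>    beam_energy d_end target_region  f_value reject
#>          <dbl> <dbl> <chr>            <dbl> <lgl> 
#>  1        98.3   5.9 prostate         3.64  FALSE 
#>  2       101.    5.4 RW               3.08  FALSE 
#>  3       103.    5.2 RW               0.901 FALSE 
#>  4       105.    5   RW               0.708 FALSE 
#>  5       105.    4.9 ERB              0.429 FALSE 
#>  6       106.    4.8 ERB              2.56  FALSE 
#>  7       108.    4.6 ERB              0.345 FALSE 
#>  8       109.    4.4 ERB             68.5   TRUE  
#>  9       112.    3.9 ERB            560.    TRUE  
#> 10       116.    3.4 ERB           1071.    TRUE
```

Spots stopping in the prostate or rectal wall, and the run whose Bragg
peak just reaches the balloon surface (`d_end` = 4.6 cm), stay below the
critical value (≈ 8.40 for F(3, 58) at the 0.01% level); every spot
depositing in the silicon mixture rejects the single-line model, with F
growing as the beam penetrates deeper.

Fitting the area–distance law on a quantification layer and inverting it:

```r
quant <- detect_campaign(camp, layer = "Raw")
model <- fit_range_model(dplyr::transmute(quant, d_end, area = silicon_area))
glance(model)
#> # A tibble: 1 × 5
#>   r.squared sigma     n slope intercept
#>       <dbl> <dbl> <int> <dbl>     <dbl>
#> 1     0.984  32.5     4 -390.     1733.

predict_distance(model, quant$silicon_area[quant$d_end == 3.9])
#> [1] 3.875824
```

The slope is negative — the peak area grows as `d_end` shrinks — and the
inverse prediction recovers the planned 3.9 cm within a millimetre. On the
published predicted-distance table, `rmse_mm()` reproduces the printed
0.83 mm RMSE for the main campaign without background suppression:

```r
d <- published_range_predictions()
with(subset(d, campaign == "main" & suppression == "none"),
     rmse_mm(predicted_cm, expected_cm))
#> [1] 0.8321658
```

## Command line

A thin CLI over the same functions lives in `inst/cli/pgsrange.R`:

```sh
Rscript inst/cli/pgsrange.R simulate --campaign main --seed 1 --out main_archive
Rscript inst/cli/pgsrange.R validate main_archive --campaign main
Rscript inst/cli/pgsrange.R detect main_archive --layer All --report report.csv
Rscript inst/cli/pgsrange.R rangefit report.csv --out model.yaml
```
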