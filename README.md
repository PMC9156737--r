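# pollenclim

Quantitative reconstruction of past precipitation from fossil pollen
assemblages, with honest uncertainty about which wiggles in the
reconstruction are real.

The package is aimed at paleoecologists and paleoclimatologists working
with compositional proxy data (pollen, diatoms, chironomids) who need the
standard calibration chain *and* a principled way to decide which
centennial-to-orbital-scale changes in the resulting series are
statistically significant, and how strong they are relative to one
another.

## What it implements

**WA-PLS transfer function.** For a samples × taxa matrix of square-root
transformed proportions *Y* (row sums *y*<sub>i+</sub>, column sums
*y*<sub>+k</sub>) and climate variable *x*, Weighted Averaging–Partial
Least Squares builds components from weighted averages of residual
climate; the fitted model reduces to one taxon coefficient vector
β<sup>(c)</sup> per component count with

&nbsp;&nbsp;&nbsp;&nbsp;x̂<sub>i</sub> = Σ<sub>k</sub> y<sub>ik</sub> β<sup>(c)</sup><sub>k</sub> / Σ<sub>k</sub> y<sub>ik</sub>,

so prediction is an abundance-weighted average over shared taxa. Fitting
(`wapls()`), prediction (`predict()`), leave-one-out cross-validation
with R², RMSEP and maximum bias (`wapls_loo()`, `performance_stats()`),
and VIF collinearity screening (`vif()`) are included. One-component
WA-PLS reduces exactly to classical Weighted Averaging with inverse
deshrinking.

**Analogue quality control.** Minimum squared-chord distances
d(p,q) = Σ(√p − √q)² between fossil and modern assemblages, classed
good / fair / non-analogue against the 5th and 10th percentiles of the
modern–modern pairwise distance distribution (`classify_analogues()`).

**SnSiZer significance map.** `snsizer()` smooths the irregular
reconstruction with a Nadaraya–Watson Gaussian kernel across a log-spaced
bandwidth grid and tests, per (time, scale) pixel, whether the derivative
of the smooth is significantly positive or negative at a row-wise
simultaneous level. Feature strength is the scale-normalized derivative
h·∂L/∂t (the derivative in the dimensionless coordinate ξ = t/h), which
is comparable *across* smoothing levels: for A·sin(ωt), its peak over
scales is A·e<sup>−1/2</sup> whatever ω. `extract_intervals()` cuts a
scale row into maximal significant runs — the humid/arid periods;
`plot()` renders the familiar red/blue/grey map against log₁₀(h).

**Synthetic test bed.** Seeded generators for unimodal Gaussian
taxon–climate responses, multinomial modern calibration sets, irregular
climate histories with prescribed humid events (two-regime 96/447-yr
sampling over 197 kyr), and fossil records (`make_taxon_responses()`,
`simulate_modern_trainingset()`, `simulate_climate_history()`,
`simulate_fossil_record()`), plus a one-call `run_pipeline()` driven by a
YAML configuration.

## Worked example

Simulate a calibration set and a 197-kyr fossil record with two humid
events (+300 mm/yr at 150–130 and 60–40 kyr BP), fit and cross-validate
the transfer function, check analogues, reconstruct, and map significant
changes:

```r
library(pollenclim)

resp   <- make_taxon_responses(25, gradient = c(200, 800), seed = 101)
x      <- seq(200, 800, length.out = 150)
modern <- simulate_modern_trainingset(resp, x, depth = 400, seed = 102)
ytr    <- sqrt_transform(to_proportions(modern$assemblage))

wapls_loo(ytr, modern$climate$x, ncomp = 5)
#> WA-PLS leave-one-out cross-validation (n = 150)
#>           r2  rmsep max_bias
#> comp1 0.9969 9.7391   9.3112
#> comp2 0.9970 9.6039  11.4467
#> comp3 0.9970 9.5347  10.8509
#> comp4 0.9970 9.5600  10.1939
#> comp5 0.9969 9.7341   9.5641
#> Selected: 2 component(s)  [note: CV-optimal RMSEP at 3 component(s)]
```

R² is the squared correlation of held-out predictions with observations;
RMSEP is in mm/yr (here ~1.6% of the 600 mm/yr gradient — synthetic data
are kind); max bias is the worst mean residual over ten gradient
segments. Two components are kept, the usual choice for noisy data.

```r
fit    <- wapls(ytr, modern$climate$x, ncomp = 2)
sched  <- history_schedule(range_kyr = c(0, 197000), baseline = 400,
            events = data.frame(start = c(150000, 60000),
                                end = c(130000, 40000),
                                amplitude = 300, ramp = 4000),
            noise_sd = 30, n_samples = 438)
hist   <- simulate_climate_history(sched, seed = 103)
fossil <- simulate_fossil_record(resp, hist, depth = 400, seed = 104)

classify_analogues(to_proportions(fossil), to_proportions(modern$assemblage))
#> Analogue QC: 455 fossil samples vs reference of modern-modern pairs
#>   thresholds: t5 = 0.033917, t10 = 0.054795
#>   good 99.56%, fair 0.44%, non-analogue 0.00%

recon <- predict(fit, sqrt_transform(to_proportions(fossil)), ncomp = 2)
sz    <- snsizer(fossil$ages, recon)
summary(sz)
#> SnSiZer map: 50 scales x 401 time points (n = 455, alpha = 0.05)
#>   pixel states: increase 15.2%, decrease 22.3%, none 43.3%, insufficient 19.3%
#>   scales: 422.4-9.816e+04 (log10 2.63-4.99); highlighted: 1604, 6091, 2.585e+04
#>   ...
#>   h = 6091: 4 significant interval(s)
#>     increase 1.5997e+05 -> 1.4132e+05 (peak |h dL/dt| = 123.2)
#>     decrease 1.3985e+05 -> 1.1825e+05 (peak |h dL/dt| = 80.58)
#>     increase 71135 -> 50031 (peak |h dL/dt| = 108.1)
#>     decrease 48558 -> 29908 (peak |h dL/dt| = 141)
#> (output truncated)
```

At the middle highlighted smoothing level (h ≈ 6.1 kyr) the map finds
significant precipitation increases at ~160–141 and ~71–50 kyr BP —
the onsets of the two prescribed humid events — and matching decreases
at their terminations; the peak scale-normalized derivatives (mm/yr per
dimensionless time unit) let the strengths be compared across smoothing
levels. `plot(sz)` draws the red/blue map; `extract_intervals(sz, h)`
returns the interval table.

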