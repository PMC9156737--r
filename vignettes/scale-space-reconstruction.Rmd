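---
title: "Pollen-based precipitation reconstruction and scale-space significance mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-based precipitation reconstruction and scale-space significance mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenclim)
```

# The problem

Fossil pollen assemblages from long lacustrine sediment cores record how
terrestrial vegetation tracked climate over glacial-interglacial time
scales. Given a *modern* calibration set — thousands of surface pollen
samples, each paired with present-day climate — a transfer function can
translate a fossil assemblage into a quantitative climate estimate, here
precipitation in mm/yr. Two statistical problems dominate the workflow:

1. **Calibration.** Taxon abundances respond unimodally and nonlinearly to
   climate, the data are closed compositions of counts, and the gradient in
   the calibration set is wide. The de facto standard estimator for this
   situation is Weighted Averaging–Partial Least Squares (WA-PLS).
2. **Inference on the reconstruction.** The reconstructed series is noisy
   and irregularly sampled; naive reading of wiggles invites
   over-interpretation. A scale-space approach asks, at every smoothing
   level simultaneously, *where is the series significantly increasing or
   decreasing*, and — the refinement implemented here — *how strong is that
   change relative to changes found at other smoothing levels*.

`pollenclim` implements the full chain with a synthetic
species–environment generator, so that every stage can be validated
end-to-end without any external database.

# The WA-PLS transfer function

Let $Y$ be the $n \times m$ matrix of square-root transformed proportions
(the transform damps dominant taxa and stabilises multinomial variance),
with row sums $y_{i+}$ and column sums $y_{+k}$, and let $x$ be the
climate variable. Component $c$ is built from the current residuals
$r_i$ (initially $x_i - \bar x$ with $\bar x$ the $y_{i+}$-weighted mean):

* taxon scores $u_k = \sum_i y_{ik} r_i / y_{+k}$ (weighted averaging of
  residuals),
* sample scores $z_i = \sum_k y_{ik} u_k / y_{i+}$,
* orthogonalisation of $z$ against earlier components under weights
  $y_{i+}$, standardisation to weighted mean 0 and variance 1,
* weighted least-squares regression of $x$ on all components so far; the
  residuals seed the next component.

Every step is affine in taxon space, and because the weighted-average
operator maps the constant taxon vector to the constant sample vector, all
intercepts can be absorbed into one coefficient vector per component
count:
$$\hat x_i = \frac{\sum_k y_{ik}\,\beta^{(c)}_k}{\sum_k y_{ik}}.$$
This is the representation `wapls()` stores, and it is what makes
prediction for fossil samples a plain weighted average over shared taxa —
and therefore invariant to rescaling any sample's counts. With $c = 1$
the procedure collapses exactly to classical Weighted Averaging with
weighted inverse deshrinking; the test suite checks this equivalence
against an independently coded WA oracle at tolerance $10^{-8}$.

Model choice follows the conventions of calibration practice:
leave-one-out cross-validation (`wapls_loo()`) reports, per component
count, $R^2$ (squared Pearson correlation of held-out predictions vs
observations), RMSEP, and maximum bias (largest absolute mean residual
across ten equal-width segments of the observed gradient; ten is the
convention of the common calibration programs — the segment count is not
standardised anywhere, so it is fixed and documented here). The default
*selected* component count is 2: with noisy compositional data, later
components chase noise even when apparent errors keep falling. The
apparent (training) error is guaranteed non-increasing in $c$ only in the
row-sum-weighted metric that the algorithm optimises; the package's
monotonicity test uses that metric.

Collinearity among candidate climate variables is screened with variance
inflation factors (`vif()`), $1/(1 - R^2_j)$ from ordinary least squares
of each variable on the others, with the field's customary flag at 20.
Exactly collinear variables report `Inf` rather than an error, since a
screening tool should describe the degeneracy, not crash on it.

# Analogue quality control

Reconstruction is only as credible as the similarity between fossil and
modern assemblages. `classify_analogues()` computes each fossil sample's
minimum squared-chord distance
$d(p, q) = \sum_k (\sqrt{p_k} - \sqrt{q_k})^2$ to the modern set and
classes it against the 5th and 10th percentiles of a reference
distribution: below the 5th percentile is a good analogue, between the
5th and 10th fair, above that non-analogue. The reference population is
taken to be all modern–modern pairwise distances ($n(n-1)/2$ values); the
phrase "all distances" is genuinely ambiguous in the literature, so the
choice is recorded in the report object and in every exported file.
Percentiles interpolate linearly between order statistics
(`quantile()` type 7), again so that results are exactly reproducible.
Distances are computed on untransformed proportions — the square root is
already inside the chord formula, and transforming first would apply it
twice.

# The scale-space significance map

## Smoothing

For an irregular series $(t_i, y_i)$ (ages in calendar years BP, larger =
older), the smooth at bandwidth $h$ is the Nadaraya–Watson estimator
$$L(t, h^2) = \frac{\sum_i K_h(t - t_i)\, y_i}{\sum_i K_h(t - t_i)},$$
with $K$ the standard Gaussian density. The NW form matters: it tends to
the mean of the signal as $h \to \infty$, which keeps the
scale-normalized derivative bounded over the whole scale grid (a
local-linear smooth would not).

## Scale-normalized derivatives

Smoothing dilutes derivatives, so the raw $\partial L / \partial t$
cannot be compared across smoothing levels. Measuring change in the
dimensionless coordinate $\xi = t/h$ instead gives the scale-normalized
derivative
$$\frac{\partial L}{\partial \xi} = h\,\frac{\partial L}{\partial t},$$
the $\gamma$-normalized derivative with $\gamma = 1$ and derivative order
$m = 1$ (the general $\gamma$ is deliberately not implemented; nothing in
the pipeline needs it). For a sinusoid $A \sin(\omega t)$ the Gaussian
convolution smooth is $A e^{-\omega^2 h^2 / 2} \sin(\omega t)$, so the
peak of $|h\,\partial L/\partial t|$ over scales is $A e^{-1/2}$
*independent of frequency* — the property that makes colour intensity
comparable between rows of the map. Both the closed-form smooth and this
amplitude law are enforced by the acceptance tests (1% and 2%
tolerances).

## Significance states

At each pixel (grid time $t$, scale $h$) the derivative is a linear
smoother $\sum_i w_i(t, h)\, y_i$, with variance
$\hat\sigma^2(h) \sum_i w_i^2$. The noise level $\hat\sigma^2(h)$ comes
from the NW residuals at that same scale, with divisor
$n - \operatorname{tr}(S_h)$ (clamped at 1): on irregular designs,
difference-based global estimators assume a regular spacing the data do
not have, while scale-specific residuals adapt automatically.

Row-wise simultaneous inference uses the expected-crossings (Rice /
Euler-characteristic) bound for the discrete t-field of standardized
derivatives. With $\kappa(h) = \sum_j \sqrt{2 (1 - \rho_j)}$ summed over
adjacent unmasked pixel pairs ($\rho_j$ the correlation of their weight
vectors) and $\nu(h) = n - \operatorname{tr}(S_h)$, the row quantile $q$
solves
$$2\,P(T_\nu > q) + \frac{\kappa}{\pi}\Bigl(1 + \frac{q^2}{\nu}\Bigr)^{-(\nu-1)/2} = \alpha .$$
For a dense design $\kappa \to T\sqrt{3/2}\,/h$, the continuous Rice
bound for Gaussian-derivative filtering of white noise. Two remarks on
this design choice:

* Simpler block-count corrections of the form $n / \overline{ESS}$
  calibrate the *smooth*, whose correlation length is about
  $\sqrt{2\pi}\,h$; the *derivative* field decorrelates on the shorter
  scale $\sim h$, and in simulation such corrections let the row-wise
  false-positive rate reach 2–3 times the nominal level. The crossing
  bound is exact for the quantity that actually matters here — the
  maximum of the standardized derivative field along a row.
* Because the Rice bound dominates the true excursion probability, the
  realised row-wise rate sits at or slightly below $\alpha$; the package's
  Monte-Carlo acceptance test (500 pure-noise replicates, $n = 200$,
  $\alpha = 0.05$) observes a maximum row rate of about 0.05.

A pixel is coloured `increase`/`decrease` when the interval
$\text{deriv} \pm q\,\text{se}$ excludes zero, in the *toward-present*
sign convention: ages grow into the past, so the derivative with respect
to age is negated and "increase" means the signal rises as time runs
from past to present — the direction in which these maps are read.
Pixels whose effective sample size
$ESS(t,h) = \sum_i K_h(t - t_i)/K_h(0)$ falls below `ess_min` (default
5, the classic SiZer convention; the cutoff is configurable because the
original sources only show the mask, not the threshold) are masked as
`insufficient` regardless of the test.

## Grids, highlights, intervals

Defaults: 50 bandwidths equally spaced in $\log_{10} h$ from twice the
median sampling interval (below which almost everything is masked) to
half the time range (above which the smooth is essentially the global
mean), and a regular 401-point time grid. Three highlighted smoothing
levels — the rows nearest the 25/50/75% quantiles of the log-scale range
— mirror the customary presentation of cutting the map at a few levels;
`extract_intervals()` turns maximal runs of significant pixels at one
row into intervals with outer-pixel-edge endpoints, ordered past to
present, each carrying the peak $|h\,\partial L/\partial t|$ as its
magnitude. Requesting a bandwidth that is not exactly a scale row is an
error: silent snapping to the nearest row would make reported intervals
depend on an invisible choice.

Numerical edge cases are handled explicitly: kernel mass that underflows
(far extrapolation at tiny $h$) yields `NA` derivatives and an
`insufficient` state; an exactly constant series short-circuits to
all-`none` states, since 0/0 t-statistics would otherwise be decided by
floating-point dust; magnitude shading normalises by the largest
scale-normalized derivative among significant pixels of the whole map,
because only relative, cross-scale-comparable intensity is meaningful.

# The synthetic test bed

`make_taxon_responses()` draws Gaussian (unimodal) response curves —
optima uniform on the gradient, tolerances uniform on 8–25% of the
gradient width, heights log-uniform over one decade. Gaussian curves are
the minimal model satisfying the unimodality assumption WA-PLS is built
on; tolerances much below 8% leave gradient gaps no taxon covers, much
above 25% make every curve flat enough that the calibration problem
becomes trivial. `simulate_modern_trainingset()` draws multinomial
counts at a given depth (pollen sum); plain multinomial noise is the
simplest counting model consistent with pollen data, and an
overdispersion mechanism was deliberately left out of the default so
that test expectations stay analytic.

`history_schedule()`/`simulate_climate_history()` build an irregular
age series with exponential gaps in two regimes — by default a mean
spacing of 96 yr in the most recent 30 kyr and 447 yr before that,
over 0–197 kyr BP, emulating the resolution structure of long
lacustrine pollen records — and a trajectory of baseline plus
trapezoidal humid events (ramped boxcars) with Gaussian noise
(default baseline 400 mm/yr, range roughly 200–800 mm/yr). When a
target sample count is requested, both regime spacings are scaled by a
common factor, preserving the resolution contrast.
`simulate_fossil_record()` closes the loop by drawing assemblages from
the same response curves along the simulated history.

What the generator does *not* emulate — and what green tests therefore do
not demonstrate about real data: spatial autocorrelation in the modern
set, secondary environmental gradients, taphonomic and
pollen-productivity biases, age-model uncertainty, and overdispersion
beyond multinomial counting noise. Real calibration sets yield far lower
cross-validated $R^2$ than the synthetic one (where the generative model
and the estimator's assumptions coincide by construction); the synthetic
results validate the *machinery*, not field performance.

# Problem sizes and reproducibility

The validation experiments run at: 500 pure-noise replicates ($n = 200$,
14 scale rows, 101 grid points) for the false-positive study; 200
replicates ($n = 300$) for the ramp power study; $n = 300$, $m = 30$,
depth 400 for cross-validated gradient recovery; and a 197-kyr two-event
history with ~438 irregular fossil samples for the end-to-end pipeline.
These sizes give Monte-Carlo errors comfortably below the margins being
tested while keeping the whole suite runnable in minutes on one core.
Every stochastic step takes an explicit seed, generators restore the
global RNG state (so they are pure functions of their arguments), and
the pipeline derives per-stage seeds deterministically from one master
seed — identical configurations reproduce byte-identical outputs.

# Known limitations

* WA-PLS standard errors are not bootstrapped; the cross-validation
  report is the only uncertainty statement on the reconstruction, and
  the significance map treats the reconstructed series as data.
* The significance machinery assumes independent homoscedastic noise
  around the smooth at each scale; strongly autocorrelated residuals
  would inflate apparent significance at small scales.
* Only the $\gamma = 1$, first-derivative normalization is implemented.
* Harmonization is single-pass by design; maps with transitive chains
  must be flattened by the user, and the package refuses rather than
  guesses.
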