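---
title: "Quantifying temporal dynamics of LST responses to forest loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal dynamics of LST responses to forest loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstdyn)
```

## The problem

Forest loss changes the land surface temperature (LST) of the affected
pixel through biophysical pathways: cleared land reflects more shortwave
radiation (albedo rises, which cools) and transpires less water (latent
heat falls, which warms). Static before/after comparisons conflate the
immediate response with the slow response of whatever succeeds the forest —
crops, cities, or regrowing vegetation. `lstdyn` implements a
space-and-time scheme that separates these timescales: it decomposes each
pixel's 10-day LST series into a piecewise-linear trend and a segmented
harmonic seasonal cycle, detects abrupt changes, pairs each forest-loss
pixel with nearby undisturbed forest controls, and quantifies the abrupt,
gradual, and seasonal components of the response, attributing them to
albedo and latent-heat changes through a surface-energy-balance expansion.

## The decomposition model

A pixel's series at composite step $t$ (36 steps per year) is

$$y_t = T_t + S_t + e_t,$$

where the trend is piecewise linear over $m+1$ segments,
$T_t = a_i + b_i t$ for $\tau^*_{i-1} < t \le \tau^*_i$, and the seasonal
component is a second-order harmonic with segment-wise coefficients,

$$S_t = \sum_{h=1}^{2} \gamma_{j,h} \sin\!\frac{2\pi h t}{36} +
        \delta_{j,h} \cos\!\frac{2\pi h t}{36},
  \qquad \tau^\#_{j-1} < t \le \tau^\#_j.$$

Up to three abrupt changes are allowed per component. Published
implementations of this model family sample break configurations with
Bayesian machinery; `lstdyn` uses a deterministic surrogate with the same
model form:

1. **Exact segmentation by dynamic programming.** For a candidate response
   (the series minus the current estimate of the other component), the
   residual sum of squares of every admissible segment is computed from
   cached prefix cross-products, and the optimal placement of $k$ breaks is
   found exactly for every $k \le 3$. Ties resolve toward earlier break
   dates for determinism.
2. **Model size by BIC.** The number of breaks per component minimizes
   $n\log(\mathrm{RSS}/n) + p\log n$, where $p$ counts segment coefficients
   plus break positions. The RSS is floored at a $10^{-3}$ K rms
   resolution scale so that numerically perfect fits (noise-free input) do
   not let BIC chase floating-point dust.
3. **Alternation.** Seasonal segmentation is fitted on the detrended
   series, trend segmentation on the deseasonalized series, for up to 5
   rounds or until the RSS stabilizes (relative change below $10^{-8}$).
   The initial trend proxy is the series of per-year means: harmonics of
   period 36 average to exactly zero over a year, so this start is
   seasonal-free and already carries year-aligned steps.
4. **Joint polish.** Conditional alternation cannot move a trend break and
   a seasonal break that sit at the same date, so the final break positions
   are refined by a local search (radius 6 steps, pairwise grids for nearby
   break pairs) against the joint least-squares objective, with a full
   joint OLS of both components given the positions. If the polish improves
   the fit, the alternation is restarted from the polished components (at
   most 3 restarts). On noise-free inputs this recovers simultaneous
   trend and seasonal breaks to machine precision.

Minimum segment lengths are 72 steps (2 years) for the trend — a slope
needs two annual cycles to be identified against the seasonal component —
and 36 steps (1 year) for the seasonal segments, the minimum that
identifies four harmonic coefficients cleanly. Missing composites are
simply absent rows: segment costs, minimum lengths (measured in real time
steps) and the time axis all account for them natively.

**Break-date confidence intervals** come from a residual bootstrap
(default 100 replicates): residuals are resampled with replacement onto
the fitted series and each component's break dates are re-estimated with
the other component held fixed; the interval is the 2.5/97.5 percentile of
the re-estimated dates, widened if necessary to contain the point
estimate. The interval machinery reuses the cached segment factorizations,
which is what keeps Monte-Carlo calibration runs tractable.

## Pairing rules

A loss event is analysed only when a detected abrupt change matches it:
the loss year must lie inside the break's confidence interval and differ
from the break year by at most two years. The *loss window* spans the loss
year united with all matched break years. The *study period* runs from two
years before the window (the scheme requires two pre-loss years; a
one-year variant is exposed) to the year before the confidence interval of
the next detected break begins, or to the series end.

Background controls must lie 25–50 km from the target (inclusive planar
distance in projected metres), keep stable forest cover with a
forest-change percentage below $\min(2\%, P)$ where $P$ is the target's
loss percentage, and differ in elevation by less than 100 m. A sample is
retained only when valid controls exceed 5% of the annulus. Backgrounds
combine by simple mean or inverse-distance weighting ($1/d$); both are
exposed because the choice does not drive conclusions.

## Response metrics

With annual trend levels $\bar T(y)$, the response series is
$\Delta T(y) = \delta T_o(y) - \delta T_{bg}(y)$ where
$\delta T(y) = \bar T(y) - \bar T(y_{w}-1)$ and $y_w$ is the window start.
$\Delta T_1$ is $\Delta T$ in the first full year after the window;
$\Delta T_{slope}$ is the OLS slope of the post-window $\Delta T$ values,
reported per decade. Monthly seasonal changes $\Delta S$, the amplitude
change $\Delta S_A$ (max minus min of the fitted cycle) and the phase
change $\Delta S_\phi$ (day of year of the first harmonic's maximum,
wrapped to $(-182.5, 182.5]$ days, negative = earlier) are the
corresponding before/after contrasts of the seasonal segments flanking the
window. Temporal patterns classify $(\Delta T_1, \Delta T_{slope})$
against margins of 0.001 K and 0.002 K/decade into enhanced/abrupt/
attenuated warming and cooling; when $|\Delta T_1|$ is inside its margin
the pattern is *insignificant* regardless of the slope (the taxonomy
leaves those cells unassigned; the raw signs are preserved).

**Annual trend levels carry the year-mean remainder.** The piecewise-linear
trend is a filter, and two pixels' filters differ whenever their
segmentations differ. A shared interannual climate anomaly therefore does
*not* cancel between a loss pixel and its controls if one differences the
fitted trends alone: the residual leaks into $\Delta T_{slope}$ at the
order of the anomaly's local slope, and it is common to every event that
shares the anomaly, so it does not average out over a cohort. Since the
premise of paired differencing is precisely
that shared signals cancel, `lstdyn` adds the year-mean of the remainder
$e_t$ back onto the annual trend level before differencing
(`include_remainder = TRUE`, the default in the response functions). The
shared anomaly then cancels exactly, at the cost of re-admitting
observation noise at $\sigma/6$ per annual mean. The pure fitted-trend
variant remains available.

## Energy-balance attribution

Linearizing upward long-wave radiation gives the sensitivity
$\lambda = 1/(4\varepsilon\sigma T^3)$ (K per W m$^{-2}$), evaluated at
the pixel's baseline-year mean LST with broadband emissivity
$\varepsilon = 0.97$ by default (an input, since the empirical
band-combination formula is not reproduced here). Albedo and ET series
are decomposed with the same machinery as LST; their trend and seasonal
changes convert to equivalent LST changes as
$\Delta T_\alpha = \lambda(-SW\!\downarrow \Delta\alpha)$ and
$\Delta T_{LE} = \lambda(-\Delta LE)$, with
$\Delta LE = \Delta ET \cdot \lambda_v / 864000$ (1 mm over 10 days
$\equiv$ 1 kg m$^{-2}$ per 864000 s; $\lambda_v = 2.45\times10^6$ J
kg$^{-1}$ fixed, not temperature-dependent). Sensible heat is never
estimated from data: $\Delta T_H = \Delta T - \Delta T_\alpha -
\Delta T_{LE}$ holds identically, and the same budget closes the monthly
seasonal terms. Downwelling radiation changes, ground-heat and emissivity
changes are taken as negligible for paired pixels; aerodynamic
energy-partitioning models are out of scope.

## The synthetic scene generator

Real satellite scenes cannot ship with a package, so every stage is
exercised against seeded synthetic scenes with recorded ground truth. A
scene is a grid of pixels (default 1-km spacing in planar projected
coordinates) with per-pixel LST, albedo and ET stacks plus the static
rasters the pairing stage needs (elevation, land cover, forest cover,
loss year/percentage/driver, latitude, region class).

Pixels follow the additive model the analysis assumes: a latitude-driven
climatology (mean LST $305 - 0.55|\phi|$ K; first-harmonic amplitude
$0.3|\phi|$ K peaking in July north of the equator, plus a small
second harmonic), a mild background trend, i.i.d. Gaussian noise
(default 0.5 K per composite; an AR(1) option exists), and a missing-data
mask (default 5%). All pixels share one regional interannual anomaly:
an AR(1) process across years (persistence 0.8, marginal sd 0.3 K)
interpolated smoothly between mid-year knots. Both choices are
deliberate: climate anomalies are autocorrelated, and a step-wise
anomaly would inject spurious shared break points at year boundaries
that no real scene contains.

Loss events inject, from the loss year onward, a trend step and a slope
change, a seasonal amplitude change (the harmonic pair is rescaled so the
cycle's range grows by the stated amount) and a phase shift (the harmonic
arguments are delayed by the stated days), plus albedo and ET steps.
Default event distributions mirror the strong-response cohorts reported
for real forest loss: step $\mathcal N(0.30, 0.05)$ K (fire-type abrupt
warming), slope $\mathcal N(-0.14, 0.05)$ K/decade (the global recovery
slope), amplitude $\mathcal N(0.50, 0.10)$ K (boreal-fire scale), phase
$\mathcal N(-1.8, 0.5)$ days (low-latitude advance), albedo
$\mathcal N(0.02, 0.005)$, ET $\mathcal N(-1.5, 0.5)$ mm/10 days. With
`couple_attribution = TRUE` the albedo and ET steps are instead derived
from the LST step through the energy-balance closed form with configurable
shares (default 30% albedo, 60% latent, 10% sensible), which makes
attribution recovery testable against truth. Events are placed only where
the 25–50 km annulus offers enough valid stable-forest candidates; loss
years default to the 2005–2015 convention clipped to the scene span.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes orbital/cloud artifacts and
spatially structured gaps, mixed pixels and georegistration error,
spatially varying climate anomalies (the anomaly is perfectly shared,
which is exactly the assumption the pairing scheme makes), gradual
non-piecewise trends, and real Köppen geography (the boreal flag is a
latitude threshold, default 55°).

## Numerical choices and degenerate inputs

* RSS floor $n \times 10^{-6}$ K$^2$ in BIC (measurement-resolution
  scale); interval factorizations rejected when a pivot falls below
  $10^{-10}$ relative to the diagonal.
* DP ties and refinement ties resolve to the earlier/first candidate;
  all stochastic steps (noise, bootstrap, background subsampling) are
  seeded, so every pipeline run is bit-reproducible.
* A constant series returns a flat single-segment fit with zero breaks; a
  series with under two years of non-missing data is rejected; a seasonal
  segment whose first harmonic is numerically zero flags its phase as
  undefined rather than returning an arbitrary date; a zero pre-loss
  amplitude flags the relative amplitude change as undefined.
* Pattern thresholds (0.001 K, 0.002 K/decade) are configuration
  defaults, not universal constants.

## Problem sizes used in validation

The shipped validation suite runs, on one CPU: oracle-equivalence checks
of the dynamic program against exhaustive search on short series; a
500-series break-recovery calibration (10-year series, +1 K step, 0.5 K
noise) with bootstrap interval coverage; and a 200-event cohort on a
60 x 60 km scene spanning 2003–2018 with 20 background controls per event,
used for both metric recovery and attribution-share recovery. These sizes
are the package's choices for a desk-scale demonstration; the upstream
global analysis they emulate involved two decades of satellite data and is
not reproducible here.

## Known limitations

* The decomposition is a deterministic surrogate for a Bayesian
  change-point family: it reports bootstrap confidence intervals, not
  posterior probabilities, and ranks candidate breaks by RSS reduction.
* Break counts above three per component are out of scope by design.
* The pairing stage assumes a single scene tile in one planar projection;
  geodesic distances and cross-tile matching are not implemented.
* Zonal confidence intervals treat events as independent; spatial
  autocorrelation among nearby events is not modelled.
* Monthly relative seasonal changes divide by near-zero seasonal values in
  transition months; only the relative amplitude change is reported as a
  headline metric, with a zero guard.

## A short tour

```{r tour, eval = FALSE}
cf <- scene_config(nrow = 60, ncol = 60, pixel_size = 1000,
                   start_year = 2003, end_year = 2018,
                   n_events = 10, seed = 1)
run <- run_all(cf, out_dir = "demo_out", max_backgrounds = 20)
run$metrics[, c("event_id", "dT1", "dT_slope", "dS_A", "dS_phi",
                "pattern")]
run$zonal
```
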