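# lstdyn

Temporal dynamics of land surface temperature (LST) responses to forest
loss, from 10-day composite time series.

Forest loss perturbs the surface energy balance: cleared land reflects
more sunlight (higher albedo, cooling) and transpires less water (lower
latent heat, warming). Which effect wins — and for how long — depends on
what replaces the forest. Static before/after comparisons mix the
immediate response with the slow imprint of cropland management, urban
growth, or vegetation regrowth. `lstdyn` separates those timescales with
a space-and-time scheme built around change detection:

1. **Decompose** each pixel's 10-day LST series (period λ = 36 steps/year)
   as `LST_t = T_t + S_t + e_t`, with a piecewise-linear trend
   `T_t = a_i + b_i t` and a segmented second-order harmonic seasonal
   cycle `S_t = Σ_h γ_{j,h} sin(2πht/36) + δ_{j,h} cos(2πht/36)`, detecting
   up to three abrupt changes per component by exact dynamic-programming
   segmentation with BIC model selection and bootstrap confidence
   intervals on break dates (an Rcpp core keeps this fast).
2. **Pair** each forest-loss pixel whose loss matches a detected abrupt
   change (loss year inside the break's confidence interval, at most two
   years apart) with stable-forest background controls 25–50 km away, on
   similar elevation (< 100 m difference) with forest-change below
   min(2%, P).
3. **Quantify** the background-corrected response: the yearly series
   ΔT = δT_o − δT_bg, its abrupt part ΔT₁ (one year after loss) and
   gradual part ΔT_slope (post-loss OLS slope, K/decade), monthly seasonal
   changes ΔS, amplitude change ΔS_A (max − min of the cycle), and phase
   change ΔS_φ (days; negative = earlier), then classify the temporal
   pattern (enhanced/abrupt/attenuated warming or cooling) from the signs
   of ΔT₁ and ΔT_slope against 0.001 K and 0.002 K/decade margins.
4. **Attribute** the response through the energy-balance linearization
   ΔT = ΔT_α + ΔT_LE + ΔT_H with sensitivity 1/(4εσT³): albedo changes
   contribute −SW↓·Δα, evapotranspiration changes convert to latent-heat
   flux (ΔLE = ΔET·λ_v/864000), and sensible heat closes the budget as the
   residual.

Because the upstream satellite archives cannot ship with a package, a
seeded synthetic scene generator produces raster scenes with the
statistical structure the analysis assumes — piecewise trends, harmonic
seasonality, a shared interannual climate anomaly, missing data, and
injected loss events with known truth — so every stage is validated by
parameter recovery. See the methods vignette
(`vignettes/lst-dynamics-methods.Rmd`) for the model, the estimation
algorithm, and all tunable parameters.

## Worked example

```r
library(lstdyn)

cf <- scene_config(nrow = 26, ncol = 26, pixel_size = 4000,
                   start_year = 2003, end_year = 2018, n_events = 6,
                   loss_year_range = c(2006, 2012), seed = 42,
                   min_valid_candidates = 10)
run <- run_all(cf, max_backgrounds = 8, bootstrap_reps = 50)
run
```

```
<lst_run> 5 events analysed (1 excluded)
  mean dT1 = +0.239 K, dT_slope = -0.109 K/decade
  mean dS_A = +0.398 K, dS_phi = -1.15 days
  dominant pattern: attenuated warming
```

The six injected events carry a +0.30 K step, a −0.14 K/decade recovery
slope, a +0.5 K amplitude increase and a 1.8-day phase advance; the run
recovers abrupt warming followed by a declining trend, an amplified
seasonal cycle and an earlier seasonal peak, and labels the cohort
"attenuated warming" — warming that fades as the surface recovers. The
cohort means sit below the injected values because one pixel's seasonal
change went undetected (its ΔS terms are zero) and single-event estimates
carry 0.5 K composite noise; the 200-event validation cohort in
`scripts/acceptance.R` recovers the injected values to within a few
hundredths. One event is excluded because its post-loss span is too short
to fit a slope, the same filter the real analysis applies. Per-event rows
live in
`run$metrics`; zonal summaries with t-based 95% confidence intervals in
`run$zonal`; yearly ΔT trajectories in `run$delta_t`; energy-balance
terms in `run$attribution`.

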