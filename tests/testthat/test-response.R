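# Fits for a small paired setup reused across tests: one target with an
# injected event, two noiseless stable backgrounds.
paired_fits <- function(step = 1, slope = 0, amplitude = 0, phase = 0,
                        noise_sd = 0, seed = 1) {
  target <- demo_event_bundle(step = step, slope = slope,
                              amplitude = amplitude, phase = phase,
                              loss_year = 2008, n_years = 12,
                              noise_sd = noise_sd, seed = seed)
  bg <- lapply(1:2, function(i)
    make_pixel_series(trend = list(intercept = 280 + i, slope = 0),
                      harmonic = c(15, 3, 0.7, -0.4), n_years = 12,
                      start_year = 2003, noise_sd = noise_sd,
                      seed = 100 + i))
  list(target = fit_decomposition(target$lst, bootstrap_reps = 0),
       backgrounds = lapply(bg, fit_decomposition, bootstrap_reps = 0),
       window = list(start = 2008, end = 2008),
       period = list(start = 2006, end = 2014, usable = TRUE))
}

test_that("identical target and background give a zero response", {
  s <- make_pixel_series(trend = list(intercept = 285, slope = 0.001),
                         harmonic = c(15, 3, 0.7, -0.4), n_years = 12,
                         start_year = 2003, noise_sd = 0.3, seed = 9)
  fit <- fit_decomposition(s, bootstrap_reps = 0)
  win <- list(start = 2008, end = 2008)
  per <- list(start = 2006, end = 2014)
  dT <- delta_trend_series(fit, list(fit), win, per)
  expect_equal(dT$dT, rep(0, nrow(dT)))
  expect_equal(delta_seasonal(fit, list(fit), win)$dS, rep(0, 12))
})

test_that("a constant target offset propagates into every post-loss dT", {
  pf <- paired_fits(step = 1)
  dT <- delta_trend_series(pf$target, pf$backgrounds, pf$window, pf$period)
  post <- dT$dT[dT$year > 2008]
  expect_equal(post, rep(1, length(post)), tolerance = 1e-6)
  expect_equal(abrupt_change(dT, pf$window), 1, tolerance = 1e-6)
  # pre-baseline year is exactly zero by construction
  expect_equal(dT$dT[dT$year == 2007], 0, tolerance = 1e-9)
})

test_that("IDW background combination follows the 1/d weighting", {
  # hand evaluation: dT 1 and 3 K at 25 and 50 km -> (1/25*1 + 1/50*3) /
  # (1/25 + 1/50) = 5/3
  M <- rbind(c(1, 1), c(3, 3))
  cb <- lstdyn:::combine_backgrounds(M, distances = c(25000, 50000),
                                     weighting = "idw")
  expect_equal(cb, rep(5 / 3, 2), ignore_attr = TRUE)
  expect_equal(lstdyn:::combine_backgrounds(M, weighting = "mean"),
               rep(2, 2), ignore_attr = TRUE)
  expect_error(lstdyn:::combine_backgrounds(M, weighting = "idw"),
               "distance")
})

test_that("injected abrupt and gradual changes are recovered noiselessly", {
  pf <- paired_fits(step = 0.39)
  dT <- delta_trend_series(pf$target, pf$backgrounds, pf$window, pf$period)
  expect_equal(abrupt_change(dT, pf$window), 0.39, tolerance = 1e-4)

  pf2 <- paired_fits(step = 0.8, slope = -0.34)
  dT2 <- delta_trend_series(pf2$target, pf2$backgrounds, pf2$window,
                            pf2$period)
  expect_equal(gradual_slope(dT2, pf2$window), -0.34, tolerance = 1e-3)
  expect_error(gradual_slope(dT2[dT2$year <= 2010, ], pf2$window),
               "3 post-loss")
})

test_that("monthly dS matches the injected harmonic change and is zero-mean", {
  pf <- paired_fits(step = 0.6, amplitude = 1.5)
  dS <- delta_seasonal(pf$target, pf$backgrounds, pf$window)
  expect_lt(abs(mean(dS$dS)), 1e-6)
  # analytic difference of the injected harmonics, aggregated to months
  base <- c(15, 3, 0.7, -0.4)
  new <- lstdyn:::shift_scale_harmonic(base, 1.5, 0)
  diff_steps <- harmonic_design(1:36, 36) %*% (new - base)
  expected <- tapply(diff_steps, rep(1:12, each = 3), mean)
  expect_equal(dS$dS, as.numeric(expected), tolerance = 1e-4)

  # no seasonal change anywhere: dS identically zero
  pf0 <- paired_fits(step = 1, amplitude = 0)
  dS0 <- delta_seasonal(pf0$target, pf0$backgrounds, pf0$window)
  expect_equal(dS0$dS, rep(0, 12), tolerance = 1e-6)
})

test_that("amplitude and phase changes are recovered with correct sign", {
  pf <- paired_fits(step = 0.6, amplitude = 2, phase = -10.139)
  cyc <- seasonal_cycle_changes(pf$target, pf$backgrounds, pf$window)
  expect_equal(cyc$dS_A, 2, tolerance = 0.02)
  expect_equal(cyc$dS_phi, -10.139, tolerance = 0.15)  # one step earlier
  base_range <- lstdyn:::harmonic_range(c(15, 3, 0.7, -0.4), 36)
  expect_equal(cyc$dS_A_rel, 100 * 2 / base_range, tolerance = 0.05)
  expect_false(cyc$phase_flag)
})

test_that("a pure second-order harmonic flags the phase as degenerate", {
  s <- make_pixel_series(trend = list(intercept = 285, slope = 0),
                         harmonic = c(0, 0, 3, 1), n_years = 12,
                         start_year = 2003)
  fit <- fit_decomposition(s, bootstrap_reps = 0)
  win <- list(start = 2008, end = 2008)
  cyc <- seasonal_cycle_changes(fit, list(fit), win)
  expect_true(cyc$phase_flag)
})

test_that("pattern classification covers the plane exactly once", {
  # paper-anchored examples
  expect_equal(as.character(classify_pattern(0.12, -0.14)$pattern),
               "attenuated warming")
  expect_equal(as.character(classify_pattern(-0.05, -0.16)$pattern),
               "enhanced cooling")
  expect_equal(as.character(classify_pattern(5e-4, 0.05)$pattern),
               "insignificant")
  expect_equal(as.character(classify_pattern(0.3, 1e-4)$pattern),
               "abrupt warming")
  expect_equal(as.character(classify_pattern(-0.3, 0.05)$pattern),
               "attenuated cooling")
  expect_equal(as.character(classify_pattern(0.3, 0.05)$pattern),
               "enhanced warming")
  expect_equal(as.character(classify_pattern(-0.3, -1e-4)$pattern),
               "abrupt cooling")

  set.seed(1)
  x <- c(runif(400, -1, 1), 0.001, -0.001, 0, 0.12)
  y <- c(runif(400, -1, 1), 0.002, -0.002, 0, -0.14)
  lab <- classify_pattern(x, y)$pattern
  expect_false(anyNA(lab))
  expect_true(all(as.character(lab) %in% lstdyn:::PATTERN_LEVELS))
})

test_that("adding a shared constant leaves all metrics unchanged", {
  pf <- paired_fits(step = 0.5, amplitude = 1, noise_sd = 0.3, seed = 21)
  shift_fit <- function(fit, k) {
    s <- fit$series
    fit_decomposition(ts10d(s$values + k, s$start_year),
                      bootstrap_reps = 0)
  }
  t2 <- shift_fit(pf$target, 3)
  b2 <- lapply(pf$backgrounds, shift_fit, k = 3)
  m1 <- response_metrics(pf$target, pf$backgrounds, pf$window, pf$period)
  m2 <- response_metrics(t2, b2, pf$window, pf$period)
  expect_equal(m1$dT1, m2$dT1, tolerance = 1e-6)
  expect_equal(m1$dT_slope, m2$dT_slope, tolerance = 1e-6)
  expect_equal(m1$dS_A, m2$dS_A, tolerance = 1e-6)
  expect_equal(m1$pattern, m2$pattern)
})
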