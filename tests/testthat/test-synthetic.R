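test_that("make_pixel_series reproduces its deterministic components", {
  # identity case: flat trend, no harmonics, no noise
  s <- make_pixel_series(trend = list(intercept = 290, slope = 0),
                         harmonic = c(0, 0, 0, 0), n_years = 5)
  expect_true(all(s$values == 290))

  # sinusoid amplitude: gamma1 = 5 gives a 10 K peak-to-trough range
  s2 <- make_pixel_series(trend = list(intercept = 0, slope = 0),
                          harmonic = c(5, 0, 0, 0), n_years = 5)
  yr <- s2$values[1:36]
  expect_equal(max(yr) - min(yr), 10, tolerance = 1e-2)

  # noise sd recovered from the truth components under a fixed seed
  s3 <- make_pixel_series(trend = list(intercept = 290, slope = 0),
                          harmonic = c(5, 2, 1, 0), n_years = 10,
                          noise_sd = 0.5, seed = 42)
  resid <- s3$values - attr(s3, "truth_trend") - attr(s3, "truth_seasonal")
  expect_gt(sd(resid), 0.45)
  expect_lt(sd(resid), 0.55)

  expect_error(make_pixel_series(trend = list(intercept = NaN, slope = 0),
                                 harmonic = c(0, 0, 0, 0), n_years = 5),
               "finite")
})

test_that("injected steps and slope changes act on the trend truth", {
  # pure step: post-loss minus pre-loss annual trend means = step exactly
  b <- demo_event_bundle(step = 0.4, loss_year = 2008)
  tr <- attr(b$lst, "truth_trend")
  pre <- mean(tr[ts10d_year_steps(b$lst, 2007)])
  post <- mean(tr[ts10d_year_steps(b$lst, 2008)])
  expect_equal(post - pre, 0.4)

  # slope change only: 10 years after onset the trend sits step*years/10 low
  b2 <- demo_event_bundle(step = 0, slope = -0.14, loss_year = 2005,
                          n_years = 16)
  tr2 <- attr(b2$lst, "truth_trend")
  tau0 <- (2005 - 2003) * 36 + 1
  t10 <- tau0 + 10 * 36  # exactly ten years after onset
  counterfactual <- 285   # flat base trend
  expect_equal(tr2[t10] - counterfactual, -0.14, tolerance = 1e-10)
})

test_that("a phase delay moves the seasonal argmax later", {
  b <- demo_event_bundle(step = 0, phase = 10, loss_year = 2008)
  se <- attr(b$lst, "truth_seasonal")
  pre_argmax <- which.max(se[ts10d_year_steps(b$lst, 2007)])
  post_argmax <- which.max(se[ts10d_year_steps(b$lst, 2009)])
  expect_equal(post_argmax - pre_argmax, 1)  # 10 days ~ 1 composite step
})

test_that("an amplitude change widens the seasonal range by the stated amount", {
  b <- demo_event_bundle(step = 0, amplitude = 2, loss_year = 2008)
  se <- attr(b$lst, "truth_seasonal")
  r_pre <- diff(range(se[ts10d_year_steps(b$lst, 2007)]))
  r_post <- diff(range(se[ts10d_year_steps(b$lst, 2009)]))
  expect_equal(r_post - r_pre, 2, tolerance = 0.05)
})

test_that("inject_loss_event rejects edge loss years", {
  s <- make_pixel_series(trend = list(intercept = 285, slope = 0),
                         harmonic = c(5, 0, 0, 0), n_years = 6,
                         start_year = 2003)
  tr <- list(loss_year = 2004, step = 1, slope = 0, amplitude = 0,
             phase = 0, albedo = 0, et = 0)
  expect_error(inject_loss_event(list(lst = s), tr), "edge")
  tr$loss_year <- 2008
  expect_error(inject_loss_event(list(lst = s), tr), "edge")
})

make_small_config <- function(n_events = 4, seed = 7, ...) {
  scene_config(nrow = 24, ncol = 24, pixel_size = 5000,
               start_year = 2003, end_year = 2014, n_events = n_events,
               loss_year_range = c(2006, 2010), seed = seed,
               min_valid_candidates = 10L, ...)
}

test_that("scenes are deterministic and honor the event count", {
  cf <- make_small_config()
  sc1 <- make_scene(cf)
  sc2 <- make_scene(cf)
  expect_identical(sc1$lst, sc2$lst)
  expect_identical(sc1$truth, sc2$truth)
  expect_equal(nrow(sc1$truth), 4L)

  cf0 <- make_small_config(n_events = 0)
  sc0 <- make_scene(cf0)
  expect_equal(nrow(sc0$truth), 0L)
  expect_true(all(is.na(sc0$loss_year)))

  expect_false(identical(make_scene(make_small_config(seed = 8))$lst,
                         sc1$lst))
})

test_that("event pixels have valid background support by construction", {
  sc <- make_scene(make_small_config(n_events = 6))
  px <- scene_pixels(sc)
  for (i in seq_len(nrow(sc$truth))) {
    ev <- sc$truth[i, ]
    tgt <- list(x = ev$x, y = ev$y,
                elevation = sc$elevation[ev$row, ev$col],
                loss_pct = ev$loss_pct)
    sel <- select_background(tgt, px)
    expect_true(sel$accepted)
    expect_gte(sel$n_valid, 10L)
  }
})

test_that("the regional anomaly is shared: stable-pixel annual differences are constant", {
  cf <- scene_config(nrow = 24, ncol = 24, pixel_size = 5000,
                     start_year = 2003, end_year = 2010, n_events = 0,
                     noise_sd = 0, missing_frac = 0, anomaly_sd = 0.5,
                     seed = 3)
  sc <- make_scene(cf)
  s1 <- scene_series(sc, 5, 5)
  s2 <- scene_series(sc, 20, 17)
  am <- function(s) vapply(2003:2010,
                           function(y) mean(s$values[ts10d_year_steps(s, y)]),
                           numeric(1))
  d <- am(s1) - am(s2)
  expect_lt(diff(range(d)), 1e-9)
})

test_that("decomposition reconstructs noiseless scene pixels (self-consistency)", {
  cf <- scene_config(nrow = 24, ncol = 24, pixel_size = 5000,
                     start_year = 2003, end_year = 2012, n_events = 2,
                     loss_year_range = c(2006, 2009), noise_sd = 0,
                     missing_frac = 0, anomaly_sd = 0, seed = 5,
                     min_valid_candidates = 10L)
  sc <- make_scene(cf)
  ev <- sc$truth[1, ]
  s <- scene_series(sc, ev$row, ev$col)
  fit <- fit_decomposition(s, bootstrap_reps = 0)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("scene generation refuses a grid too small for the ring", {
  expect_error(make_scene(scene_config(nrow = 20, ncol = 20,
                                       pixel_size = 1000, seed = 1)),
               "ring")
})
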