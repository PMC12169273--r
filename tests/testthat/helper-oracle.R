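# Independent brute-force oracle for the segmentation: enumerate all
# admissible placements of k breaks (k <= 2) over observed rows, fit each
# segment by QR least squares, and return the minimum total RSS.
exhaustive_seg_rss <- function(X, y, t, min_len, k) {
  n <- length(y)
  p <- ncol(X)
  seg_rss <- function(i, j) {
    f <- stats::lm.fit(X[i:j, , drop = FALSE], y[i:j])
    sum(f$residuals^2)
  }
  valid <- function(i, j) (t[j] - t[i] + 1) >= min_len && (j - i + 1) >= p
  if (k == 0L) {
    if (!valid(1L, n)) return(Inf)
    return(seg_rss(1L, n))
  }
  best <- Inf
  if (k == 1L) {
    for (b in seq_len(n - 1L)) {
      if (!valid(1L, b) || !valid(b + 1L, n)) next
      best <- min(best, seg_rss(1L, b) + seg_rss(b + 1L, n))
    }
  } else if (k == 2L) {
    for (b1 in seq_len(n - 2L)) {
      if (!valid(1L, b1)) next
      r1 <- seg_rss(1L, b1)
      for (b2 in seq(b1 + 1L, n - 1L)) {
        if (!valid(b1 + 1L, b2) || !valid(b2 + 1L, n)) next
        best <- min(best, r1 + seg_rss(b1 + 1L, b2) + seg_rss(b2 + 1L, n))
      }
    }
  } else stop("oracle supports k <= 2")
  best
}

# DP RSS for the same problem, via the package's cost + DP machinery.
dp_seg_rss <- function(X, y, t, min_len, k) {
  cost <- lstdyn:::cpp_seg_cost(X, y, as.integer(t), as.integer(min_len))
  lstdyn:::cpp_dp(cost, as.integer(max(k, 1L)))$rss[k + 1L]
}

# A standard single-event pixel bundle used across tests: boreal-like
# seasonal cycle, configurable injections.
demo_event_bundle <- function(step = 1, slope = 0, amplitude = 0,
                              phase = 0, loss_year = 2008, n_years = 10L,
                              noise_sd = 0, missing_frac = 0, seed = 1,
                              albedo_step = 0, et_step = 0) {
  lst <- make_pixel_series(trend = list(intercept = 285, slope = 0),
                           harmonic = c(15, 3, 0.7, -0.4),
                           n_years = n_years, start_year = 2003L,
                           noise_sd = noise_sd,
                           missing_frac = missing_frac, seed = seed)
  alb <- make_pixel_series(trend = list(intercept = 0.12, slope = 0),
                           harmonic = c(-0.02, -0.004, 0, 0),
                           n_years = n_years, start_year = 2003L,
                           noise_sd = 0, seed = seed + 1L)
  et <- make_pixel_series(trend = list(intercept = 8, slope = 0),
                          harmonic = c(5, 1, 0, 0), n_years = n_years,
                          start_year = 2003L, noise_sd = 0,
                          seed = seed + 2L)
  inject_loss_event(list(lst = lst, albedo = alb, et = et),
                    list(loss_year = loss_year, step = step, slope = slope,
                         amplitude = amplitude, phase = phase,
                         albedo = albedo_step, et = et_step))
}
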