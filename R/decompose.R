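#' Segmented trend + harmonic decomposition of a 10-day series
#'
#' Decomposes a 10-day composite series into a piecewise-linear trend and a
#' segmented second-order harmonic seasonal component (period 36 steps), and
#' detects up to `max_trend_breaks` / `max_seasonal_breaks` abrupt changes in
#' each component. The model is
#' \deqn{y_t = T_t + S_t + e_t}
#' with linear trend segments \eqn{T_t = a_i + b_i t} and seasonal segments
#' \eqn{S_t = \sum_{h=1}^{2} \gamma_{j,h}\sin(2\pi h t/36) +
#' \delta_{j,h}\cos(2\pi h t/36)}. Segmentations are found by exact
#' dynamic programming on interval residual sums of squares, alternating
#' between the two components (seasonal fit on the detrended series, trend
#' fit on the deseasonalized series) until the total RSS stabilises; the
#' number of breaks per component is selected by BIC. Break-date confidence
#' intervals come from a residual bootstrap re-estimating each component's
#' break positions with the other component held fixed.
#'
#' @param series A [ts10d] series.
#' @param max_trend_breaks,max_seasonal_breaks Maximum number of abrupt
#'   changes per component (default 3, the three most significant changes).
#' @param min_trend_seg Minimum trend segment length in steps (default 72 =
#'   2 years, so each segment identifies a slope).
#' @param min_seasonal_seg Minimum seasonal segment length in steps (default
#'   36 = 1 year, identifying the four harmonic coefficients).
#' @param ci_level Confidence level for break-date intervals (default 0.95).
#' @param bootstrap_reps Residual-bootstrap replicates for the break-date
#'   confidence intervals (default 100; 0 skips interval estimation).
#' @param seed Optional integer seed for the bootstrap.
#' @param max_iter Maximum outer alternation iterations (default 5).
#' @param tol Relative RSS change declaring convergence (default 1e-8).
#' @param .design Optional prepared design from [seg_design()] for the same
#'   observation times and minimum segment lengths; lets batch callers reuse
#'   the cached interval factorizations across pixels.
#' @return An object of class `lst_decomp` with elements:
#'   \describe{
#'     \item{trend_segments}{data.frame of `start_step`, `end_step`,
#'       `intercept`, `slope` (per-step units).}
#'     \item{seasonal_segments}{data.frame of segment bounds and harmonic
#'       coefficients `gamma1`, `delta1`, `gamma2`, `delta2`.}
#'     \item{breakpoints}{data.frame: `component` ("trend"/"seasonal"),
#'       `step` (first step of the new segment), `year`, bootstrap CI bounds
#'       in steps and years, and a `magnitude` summary (K): the jump of the
#'       trend line, or the seasonal amplitude change, at the break.}
#'     \item{trend, seasonal, residuals}{per-step component values over the
#'       full span (trend and seasonal are model-defined at missing steps;
#'       residuals are `NA` there).}
#'     \item{rss, n_iter, converged}{fit diagnostics.}
#'   }
#' @examples
#' s <- make_pixel_series(trend = list(intercept = 290, slope = 0),
#'                        harmonic = c(5, 0, 0, 0), n_years = 6,
#'                        start_year = 2003, noise_sd = 0.2, seed = 1)
#' fit <- fit_decomposition(s, bootstrap_reps = 0)
#' fit$trend_segments
#' @export
fit_decomposition <- function(series, max_trend_breaks = 3L,
                              max_seasonal_breaks = 3L,
                              min_trend_seg = 72L, min_seasonal_seg = 36L,
                              ci_level = 0.95, bootstrap_reps = 100L,
                              seed = NULL, max_iter = 5L, tol = 1e-8,
                              .design = NULL) {
  stopifnot(inherits(series, "ts10d"))
  v <- series$values
  n <- length(v)
  obs <- which(!is.na(v))
  if (length(obs) < 2L * series$period)
    stop("insufficient non-missing data: need at least 2 years of coverage")
  t_obs <- obs
  y <- v[obs]
  if (!is.null(seed)) set.seed(seed)

  # degenerate constant series: flat fit, no breaks
  if (stats::sd(y) == 0) {
    return(new_lst_decomp(
      series,
      trend_seg = data.frame(start_step = 1L, end_step = n,
                             intercept = y[1], slope = 0),
      seas_seg = data.frame(start_step = 1L, end_step = n,
                            gamma1 = 0, delta1 = 0, gamma2 = 0, delta2 = 0),
      breaks = empty_breaks(), rss = 0, n_iter = 0L, converged = TRUE))
  }

  if (is.null(.design)) {
    .design <- seg_design(t_obs, min_trend_seg, min_seasonal_seg,
                          series$period)
  } else if (!identical(.design$t, as.integer(t_obs))) {
    stop(".design was prepared for different observation times")
  }
  Xs <- .design$Xs

  # Initial trend proxy: per-year means. Harmonics of period 36 average to
  # zero over a full year, so this is seasonal-free and already carries
  # year-aligned steps, which keeps the first seasonal fit well conditioned.
  yr_obs <- (t_obs - 1L) %/% series$period
  trend_vals <- stats::ave(y, yr_obs)
  seas_vals <- rep(0, length(obs))
  trend_sel <- seas_sel <- NULL
  n_iter <- 0L
  converged <- FALSE
  rss <- Inf
  for (round in 1:3) {
    rss_prev <- Inf
    for (iter in seq_len(max_iter)) {
      n_iter <- n_iter + 1L
      detr <- y - trend_vals
      seas_sel <- select_segmentation(.design$seasonal, Xs, detr,
                                      max_seasonal_breaks, p_per_seg = 4L)
      seas_vals <- seas_sel$fitted
      deseas <- y - seas_vals
      trend_sel <- select_segmentation(.design$trend, cbind(1, t_obs),
                                       deseas - mean(deseas),
                                       max_trend_breaks, p_per_seg = 2L)
      # refit trend coefficients on the uncentered response
      trend_sel <- refit_segments(trend_sel, cbind(1, t_obs), deseas)
      trend_vals <- trend_sel$fitted
      rss <- sum((y - trend_vals - seas_vals)^2)
      if (is.finite(rss_prev) && abs(rss_prev - rss) < tol * (1 + rss)) {
        converged <- TRUE
        break
      }
      rss_prev <- rss
    }
    seas_sel <- refit_segments(seas_sel, Xs, y - trend_vals)
    seas_vals <- seas_sel$fitted
    rss <- sum((y - trend_vals - seas_vals)^2)

    if (length(trend_sel$breaks) == 0L && length(seas_sel$breaks) == 0L)
      break
    # Conditional alternation cannot move coincident trend and seasonal
    # breaks jointly; polish positions and coefficients against the joint
    # least-squares objective, and restart the alternation from the
    # polished components when that found a better optimum.
    ref <- refine_positions(y, t_obs, Xs, trend_sel$breaks,
                            seas_sel$breaks, min_trend_seg,
                            min_seasonal_seg)
    jf <- joint_fit(y, t_obs, Xs, ref$tb, ref$sb)
    if (jf$rss <= rss + 1e-12) {
      trend_sel$breaks <- ref$tb
      trend_sel$coefs <- jf$trend_coefs
      trend_sel$fitted <- trend_vals <- jf$trend
      seas_sel$breaks <- ref$sb
      seas_sel$coefs <- jf$seas_coefs
      seas_sel$fitted <- seas_vals <- jf$seasonal
      improved <- rss - jf$rss > tol * (1 + jf$rss)
      rss <- jf$rss
      converged <- TRUE
      if (!improved || round == 3L) break
    } else break
  }

  trend_seg <- segment_table(trend_sel, t_obs, n,
                             c("intercept", "slope"))
  seas_seg <- segment_table(seas_sel, t_obs, n,
                            c("gamma1", "delta1", "gamma2", "delta2"))

  resid_obs <- y - trend_vals - seas_vals
  breaks <- rbind(
    component_breaks("trend", trend_sel, trend_seg, t_obs, series,
                     prep = .design$trend,
                     fitted = trend_vals - mean(trend_vals),
                     resid = resid_obs, reps = bootstrap_reps,
                     ci_level = ci_level),
    component_breaks("seasonal", seas_sel, seas_seg, t_obs, series,
                     prep = .design$seasonal, fitted = seas_vals,
                     resid = resid_obs, reps = bootstrap_reps,
                     ci_level = ci_level)
  )

  new_lst_decomp(series, trend_seg, seas_seg, breaks, rss,
                 n_iter = n_iter, converged = converged)
}

#' Prepared segmentation design
#'
#' Precomputes the interval factorizations used by [fit_decomposition()] for
#' a given set of observation times and minimum segment lengths, so that
#' batch callers (many pixels on one time axis) can share them.
#'
#' @param t_obs Integer step indices of the non-missing observations.
#' @param min_trend_seg,min_seasonal_seg Minimum segment lengths in steps.
#' @param period Steps per year (36).
#' @return An opaque design list for the `.design` argument of
#'   [fit_decomposition()].
#' @export
seg_design <- function(t_obs, min_trend_seg = 72L, min_seasonal_seg = 36L,
                       period = 36L) {
  t_obs <- as.integer(t_obs)
  Xt <- cbind(1, (t_obs - mean(t_obs)) / length(t_obs))
  Xs <- harmonic_design(t_obs, period)
  list(t = t_obs, Xs = Xs,
       trend = cpp_seg_prepare(Xt, t_obs, as.integer(min_trend_seg)),
       seasonal = cpp_seg_prepare(Xs, t_obs, as.integer(min_seasonal_seg)))
}

# DP segmentation of one component + BIC selection of the break count.
# Returns list(k, breaks (obs indices of segment ends), fitted, coefs, rss).
select_segmentation <- function(prep, X, resp, max_breaks, p_per_seg) {
  dp <- cpp_dp_prep(prep, resp, as.integer(max_breaks))
  nobs <- length(resp)
  # RSS floor at a 1e-3 K rms resolution scale: below it segmentations are
  # indistinguishable and BIC must not chase numerical dust (noiseless input)
  floor_rss <- nobs * 1e-6
  bic <- rep(Inf, max_breaks + 1L)
  for (k in 0:max_breaks) {
    r <- dp$rss[k + 1L]
    if (!is.finite(r)) next
    p_eff <- p_per_seg * (k + 1L) + k
    bic[k + 1L] <- nobs * log(max(r, floor_rss) / nobs) + p_eff * log(nobs)
  }
  k_hat <- which.min(bic) - 1L
  br <- dp$breaks[[k_hat + 1L]]
  if (is.null(br)) br <- integer(0)
  out <- list(k = k_hat, breaks = as.integer(br), rss = dp$rss[k_hat + 1L])
  refit_segments(out, X, resp)
}

# (Re)fit per-segment OLS coefficients and fitted values at observed rows.
refit_segments <- function(sel, X, resp) {
  bounds <- c(0L, sel$breaks, length(resp))
  fitted <- numeric(length(resp))
  coefs <- matrix(0, nrow = length(bounds) - 1L, ncol = ncol(X))
  for (s in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    f <- stats::lm.fit(X[rows, , drop = FALSE], resp[rows])
    cf <- f$coefficients
    cf[is.na(cf)] <- 0
    coefs[s, ] <- cf
    fitted[rows] <- X[rows, , drop = FALSE] %*% cf
  }
  sel$coefs <- coefs
  sel$fitted <- fitted
  sel
}

# Joint OLS of both components given fixed break positions: blockwise trend
# columns (intercept, step) plus blockwise harmonic columns.
joint_fit <- function(y, t_obs, Xs, tb, sb) {
  nobs <- length(y)
  tB <- c(0L, tb, nobs)
  sB <- c(0L, sb, nobs)
  nts <- length(tB) - 1L
  nss <- length(sB) - 1L
  X <- matrix(0, nobs, 2L * nts + 4L * nss)
  for (s in seq_len(nts)) {
    rows <- (tB[s] + 1L):tB[s + 1L]
    X[rows, 2L * s - 1L] <- 1
    X[rows, 2L * s] <- t_obs[rows]
  }
  off <- 2L * nts
  for (s in seq_len(nss)) {
    rows <- (sB[s] + 1L):sB[s + 1L]
    X[rows, off + 4L * (s - 1L) + 1:4] <- Xs[rows, ]
  }
  f <- stats::lm.fit(X, y)
  cf <- f$coefficients
  cf[is.na(cf)] <- 0
  trend_coefs <- matrix(cf[seq_len(off)], nts, 2L, byrow = TRUE)
  seas_coefs <- matrix(cf[-seq_len(off)], nss, 4L, byrow = TRUE)
  trend <- seasonal <- numeric(nobs)
  for (s in seq_len(nts)) {
    rows <- (tB[s] + 1L):tB[s + 1L]
    trend[rows] <- trend_coefs[s, 1] + trend_coefs[s, 2] * t_obs[rows]
  }
  for (s in seq_len(nss)) {
    rows <- (sB[s] + 1L):sB[s + 1L]
    seasonal[rows] <- Xs[rows, , drop = FALSE] %*% seas_coefs[s, ]
  }
  list(rss = sum(f$residuals^2), trend = trend, seasonal = seasonal,
       trend_coefs = trend_coefs, seas_coefs = seas_coefs)
}

# Validity of a break-position vector: segments tile 1..nobs with the
# minimum span (in step units) respected.
breaks_valid <- function(b, t_obs, min_len) {
  nobs <- length(t_obs)
  if (length(b) == 0L) return(TRUE)
  if (any(b < 1L | b >= nobs) || is.unsorted(b, strictly = TRUE))
    return(FALSE)
  B <- c(0L, b, nobs)
  spans <- t_obs[B[-1L]] - t_obs[B[-length(B)] + 1L] + 1L
  all(spans >= min_len)
}

# Local joint search over break positions: pairwise grids for nearby
# trend/seasonal breaks, then single-break sweeps; strict-improvement,
# deterministic.
refine_positions <- function(y, t_obs, Xs, tb, sb, min_t, min_s,
                             radius = 6L) {
  rss_of <- function(tb2, sb2) joint_fit(y, t_obs, Xs, tb2, sb2)$rss
  best <- rss_of(tb, sb)
  offs <- seq(-radius, radius)
  for (pass in 1:2) {
    changed <- FALSE
    for (i in seq_along(tb)) {
      for (j in seq_along(sb)) {
        if (abs(t_obs[tb[i]] - t_obs[sb[j]]) > 3L * radius) next
        for (d1 in offs) for (d2 in offs) {
          if (d1 == 0L && d2 == 0L) next
          tb2 <- tb; tb2[i] <- tb[i] + d1
          sb2 <- sb; sb2[j] <- sb[j] + d2
          if (!breaks_valid(tb2, t_obs, min_t) ||
              !breaks_valid(sb2, t_obs, min_s)) next
          r <- rss_of(tb2, sb2)
          if (r < best - 1e-12) {
            best <- r; tb <- tb2; sb <- sb2; changed <- TRUE
          }
        }
      }
    }
    sweep_one <- function(b, other_fixed, min_len, is_trend) {
      for (i in seq_along(b)) {
        for (d in offs) {
          if (d == 0L) next
          b2 <- b; b2[i] <- b[i] + d
          if (!breaks_valid(b2, t_obs, min_len)) next
          r <- if (is_trend) rss_of(b2, other_fixed)
               else rss_of(other_fixed, b2)
          if (r < best - 1e-12) {
            best <<- r; b <- b2; changed <<- TRUE
          }
        }
      }
      b
    }
    tb <- sweep_one(tb, sb, min_t, TRUE)
    sb <- sweep_one(sb, tb, min_s, FALSE)
    if (!changed) break
  }
  list(tb = tb, sb = sb, rss = best)
}

# Segment table over the full step axis 1..n. Boundaries sit at the first
# observed step of each new segment (missing steps ahead of a break stay with
# the old segment).
segment_table <- function(sel, t_obs, n, coef_names) {
  k <- length(sel$breaks)
  starts <- c(1L, t_obs[sel$breaks + 1L])
  ends <- c(t_obs[sel$breaks + 1L] - 1L, n)
  df <- data.frame(segment = seq_len(k + 1L), start_step = starts,
                   end_step = ends)
  cf <- as.data.frame(sel$coefs)
  names(cf) <- coef_names
  cbind(df, cf)
}

empty_breaks <- function() {
  data.frame(component = character(0), step = integer(0), year = integer(0),
             ci_lo_step = integer(0), ci_hi_step = integer(0),
             ci_lo_year = integer(0), ci_hi_year = integer(0),
             magnitude = numeric(0))
}

step_to_year <- function(step, start_year, period = 36L) {
  as.integer(start_year + (step - 1L) %/% period)
}

# Break rows for one component, with residual-bootstrap CIs. The bootstrap
# holds the other component at its fitted values, so each replicate series
# for this component is its own fit plus resampled residuals.
component_breaks <- function(component, sel, seg, t_obs, series, prep,
                             fitted, resid, reps, ci_level) {
  k <- length(sel$breaks)
  if (k == 0L) return(empty_breaks())
  steps <- t_obs[sel$breaks + 1L]
  yr <- step_to_year(steps, series$start_year, series$period)
  mag <- vapply(seq_len(k), function(j) {
    segment_jump(component, seg, j, steps[j], series$period)
  }, numeric(1))
  lo <- hi <- steps
  if (reps > 0L) {
    bm <- cpp_boot_breaks(prep, fitted, resid, as.integer(k),
                          as.integer(reps))
    a <- (1 - ci_level) / 2
    for (j in seq_len(k)) {
      idx <- bm[, j]
      idx <- idx[!is.na(idx)]
      if (length(idx)) {
        st <- t_obs[idx + 1L]
        qs <- stats::quantile(st, c(a, 1 - a), type = 1, names = FALSE)
        lo[j] <- min(qs[1], steps[j])
        hi[j] <- max(qs[2], steps[j])
      }
    }
  }
  data.frame(component = component, step = as.integer(steps), year = yr,
             ci_lo_step = as.integer(lo), ci_hi_step = as.integer(hi),
             ci_lo_year = step_to_year(lo, series$start_year, series$period),
             ci_hi_year = step_to_year(hi, series$start_year, series$period),
             magnitude = mag)
}

# Magnitude summary at a break: jump of the trend line, or change in seasonal
# amplitude (max - min of the harmonic cycle), new segment minus old.
segment_jump <- function(component, seg, j, step, period) {
  old <- seg[j, ]
  new <- seg[j + 1L, ]
  if (component == "trend") {
    (new$intercept + new$slope * step) - (old$intercept + old$slope * step)
  } else {
    harmonic_range(as.numeric(new[c("gamma1", "delta1", "gamma2", "delta2")]),
                   period) -
      harmonic_range(as.numeric(old[c("gamma1", "delta1", "gamma2", "delta2")]),
                     period)
  }
}

# max - min of a second-order harmonic over one cycle (fine grid).
harmonic_range <- function(coefs, period = 36L, n_grid = 720L) {
  tg <- seq(0, period, length.out = n_grid + 1L)[-1L]
  v <- harmonic_design(tg, period) %*% coefs
  max(v) - min(v)
}

new_lst_decomp <- function(series, trend_seg, seas_seg, breaks, rss,
                           n_iter, converged) {
  n <- length(series$values)
  steps <- seq_len(n)
  trend_full <- eval_trend(trend_seg, steps)
  seas_full <- eval_seasonal(seas_seg, steps, series$period)
  structure(
    list(series = series, trend_segments = trend_seg,
         seasonal_segments = seas_seg, breakpoints = breaks,
         trend = trend_full, seasonal = seas_full,
         residuals = series$values - trend_full - seas_full,
         rss = rss, n_iter = n_iter, converged = converged),
    class = "lst_decomp")
}

eval_trend <- function(seg, steps) {
  out <- numeric(length(steps))
  for (s in seq_len(nrow(seg))) {
    in_seg <- steps >= seg$start_step[s] & steps <= seg$end_step[s]
    out[in_seg] <- seg$intercept[s] + seg$slope[s] * steps[in_seg]
  }
  out
}

eval_seasonal <- function(seg, steps, period) {
  out <- numeric(length(steps))
  for (s in seq_len(nrow(seg))) {
    in_seg <- steps >= seg$start_step[s] & steps <= seg$end_step[s]
    if (!any(in_seg)) next
    X <- harmonic_design(steps[in_seg], period)
    out[in_seg] <- X %*% as.numeric(seg[s, c("gamma1", "delta1",
                                             "gamma2", "delta2")])
  }
  out
}

#' @export
print.lst_decomp <- function(x, ...) {
  cat(sprintf(paste0("<lst_decomp> %d trend / %d seasonal segments, ",
                     "%d breaks, rss %.4g\n"),
              nrow(x$trend_segments), nrow(x$seasonal_segments),
              nrow(x$breakpoints), x$rss))
  if (nrow(x$breakpoints)) print(x$breakpoints)
  invisible(x)
}

#' Evaluate fitted components at given steps
#'
#' Piecewise evaluation of the fitted trend and seasonal components, using
#' the segment active at each step (model-defined at missing steps too).
#'
#' @param result An [fit_decomposition()] result.
#' @param steps Integer step indices inside the fitted span.
#' @return List with numeric vectors `trend` and `seasonal`.
#' @export
evaluate_components <- function(result, steps) {
  stopifnot(inherits(result, "lst_decomp"))
  n <- length(result$series$values)
  if (any(steps < 1L | steps > n)) stop("steps outside fitted span")
  list(trend = eval_trend(result$trend_segments, steps),
       seasonal = eval_seasonal(result$seasonal_segments, steps,
                                result$series$period))
}

#' Annual means of the fitted trend component
#'
#' Mean of the trend component over each calendar year's 36 steps. The trend
#' is model-defined everywhere, so steps masked in the observations still
#' contribute.
#'
#' With `include_remainder = TRUE` the year-mean of the remainder (residual)
#' series is added back. The piecewise-linear trend filters shared
#' interannual climate variability differently on different pixels, which
#' would leak into paired differences; the remainder year-mean restores the
#' part of the annual signal the linear segments smoothed away, so shared
#' anomalies cancel exactly between a pixel and its backgrounds. The
#' response metrics use this form.
#'
#' @param result An [fit_decomposition()] result.
#' @param include_remainder Add the annual remainder means (default FALSE).
#' @return data.frame with columns `year` and `trend_mean` (K).
#' @export
annual_trend_means <- function(result, include_remainder = FALSE) {
  stopifnot(inherits(result, "lst_decomp"))
  s <- result$series
  years <- s$start_year + seq_len(s$n_years) - 1L
  tm <- vapply(years, function(y) {
    steps <- ts10d_year_steps(s, y)
    m <- mean(result$trend[steps])
    if (include_remainder) {
      r <- mean(result$residuals[steps], na.rm = TRUE)
      if (is.finite(r)) m <- m + r
    }
    m
  }, numeric(1))
  data.frame(year = years, trend_mean = tm)
}
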