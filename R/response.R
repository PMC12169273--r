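#' @title LST response quantification
#' @description Background-corrected response metrics for a paired sample:
#'   the yearly trend-response series, its abrupt (one year after loss) and
#'   gradual (post-loss slope) summaries, monthly seasonal changes,
#'   seasonal amplitude/phase changes, and the temporal-pattern label.
#' @name response
NULL

# Combine per-background values (rows = backgrounds) by simple mean or
# inverse-distance weighting with weights 1/d.
combine_backgrounds <- function(M, distances = NULL,
                                weighting = c("mean", "idw")) {
  weighting <- match.arg(weighting)
  M <- rbind(M)
  if (weighting == "mean") return(colMeans(M))
  if (is.null(distances) || length(distances) != nrow(M))
    stop("idw weighting needs one distance per background")
  w <- 1 / distances
  colSums(M * w) / sum(w)
}

#' Yearly trend-response series ΔT
#'
#' For the target and each background pixel, the yearly departure of the
#' annual trend-component mean from its value one year before the loss
#' window; the response is the target departure minus the combined
#' background departure:
#' \deqn{\Delta T(y) = \delta T_o(y) - \delta T_{bg}(y), \quad
#'       \delta T(y) = \bar T(y) - \bar T(y_{w,start} - 1).}
#' Backgrounds combine by simple mean or inverse-distance weighting
#' (weights 1/d).
#'
#' @param target [fit_decomposition()] result of the forest-loss pixel.
#' @param backgrounds List of decompositions of the valid background pixels.
#' @param window [loss_window()] of the sample.
#' @param period [study_period()] of the sample.
#' @param distances Background distances in metres (required for
#'   `weighting = "idw"`).
#' @param weighting `"mean"` or `"idw"`.
#' @param include_remainder Carry the annual remainder means with the model
#'   trend (default TRUE) so that interannual climate anomalies shared by
#'   the paired pixels cancel exactly; see [annual_trend_means()].
#' @return data.frame: `year`, `years_since_loss` (relative to the window
#'   end; 1 = first full post-loss year), `dT` (K).
#' @export
delta_trend_series <- function(target, backgrounds, window, period,
                               distances = NULL,
                               weighting = c("mean", "idw"),
                               include_remainder = TRUE) {
  weighting <- match.arg(weighting)
  if (length(backgrounds) == 0L) stop("no valid backgrounds")
  years <- seq(period$start, period$end)
  base_year <- window$start - 1L
  delta_one <- function(dec) {
    atm <- annual_trend_means(dec, include_remainder = include_remainder)
    v <- atm$trend_mean[match(years, atm$year)]
    b <- atm$trend_mean[match(base_year, atm$year)]
    v - b
  }
  d_o <- delta_one(target)
  d_bg <- t(vapply(backgrounds, delta_one, numeric(length(years))))
  d_bg <- combine_backgrounds(d_bg, distances, weighting)
  data.frame(year = years, years_since_loss = years - window$end,
             dT = d_o - d_bg)
}

#' Abrupt change ΔT_1
#'
#' The trend response one year after the loss: the ΔT value in the first
#' full calendar year after the loss-window end.
#'
#' @param delta_t A [delta_trend_series()] result.
#' @param window The sample's [loss_window()].
#' @return ΔT_1 in K.
#' @export
abrupt_change <- function(delta_t, window) {
  i <- match(window$end + 1L, delta_t$year)
  if (is.na(i)) stop("post-loss span shorter than one year")
  delta_t$dT[i]
}

#' Gradual change ΔT_slope
#'
#' Ordinary least-squares slope of the post-loss ΔT values against year
#' (equivalently, the slope of the target's post-loss annual trend means
#' minus the combined background's), reported per decade.
#'
#' @param delta_t A [delta_trend_series()] result.
#' @param window The sample's [loss_window()].
#' @return ΔT_slope in K/decade.
#' @export
gradual_slope <- function(delta_t, window) {
  post <- delta_t[delta_t$year > window$end, , drop = FALSE]
  if (nrow(post) < 3L) stop("need at least 3 post-loss years for the slope")
  stats::coef(stats::lm(dT ~ year, data = post))[["year"]] * 10
}

# Seasonal segment coefficients active at a step.
seasonal_coef_at <- function(result, step) {
  seg <- result$seasonal_segments
  i <- which(step >= seg$start_step & step <= seg$end_step)[1]
  as.numeric(seg[i, c("gamma1", "delta1", "gamma2", "delta2")])
}

# Before/after seasonal coefficients around a loss window.
seasonal_before_after <- function(result, window) {
  s <- result$series
  before_step <- (window$start - 1L - s$start_year) * 36L + 36L
  after_step <- (window$end + 1L - s$start_year) * 36L + 1L
  n <- length(s$values)
  if (before_step < 1L || after_step > n)
    stop("loss window leaves no pre- or post-loss seasonal segment")
  list(before = seasonal_coef_at(result, before_step),
       after = seasonal_coef_at(result, after_step))
}

#' Monthly seasonal response ΔS
#'
#' For each pixel, the change in the seasonal component per calendar month
#' between the segments after and before the loss window; the response is
#' the target change minus the combined background change. Months aggregate
#' three consecutive composite steps. When no seasonal break was detected
#' across the window the change is identically zero.
#'
#' @inheritParams delta_trend_series
#' @return data.frame: `month` (1-12), `dS` (K).
#' @export
delta_seasonal <- function(target, backgrounds, window, distances = NULL,
                           weighting = c("mean", "idw")) {
  weighting <- match.arg(weighting)
  if (length(backgrounds) == 0L) stop("no valid backgrounds")
  month_of_step <- rep(1:12, each = 3L)
  X1 <- harmonic_design(1:36, 36L)
  monthly_change <- function(dec) {
    ba <- seasonal_before_after(dec, window)
    diff_steps <- as.numeric(X1 %*% (ba$after - ba$before))
    tapply(diff_steps, month_of_step, mean)
  }
  d_o <- monthly_change(target)
  d_bg <- t(vapply(backgrounds, monthly_change, numeric(12L)))
  d_bg <- combine_backgrounds(d_bg, distances, weighting)
  data.frame(month = 1:12, dS = as.numeric(d_o - d_bg))
}

# Day-of-year of the maximum of the first-harmonic part of a seasonal
# segment; NA when the first harmonic is degenerate.
phase_day <- function(coef, tol = 1e-9) {
  g <- coef[1]; d <- coef[2]
  if (sqrt(g^2 + d^2) < tol) return(NA_real_)
  w <- 2 * pi / 36
  t_max <- ((pi / 2 - atan2(d, g)) / w) %% 36
  t_max * DAYS_PER_STEP
}

#' Seasonal-cycle amplitude and phase changes
#'
#' Amplitude is the max minus min of the fitted seasonal cycle; phase is the
#' day-of-year at which the first-order harmonic peaks. Changes are
#' before/after differences across the loss window, background-corrected;
#' phase differences are wrapped to (-182.5, 182.5] days (negative =
#' advance). The relative amplitude change divides by the target's pre-loss
#' amplitude.
#'
#' @inheritParams delta_trend_series
#' @return List: `dS_A` (K), `dS_A_rel` (%), `dS_phi` (days),
#'   `amplitude_before` (K), `phase_flag` (TRUE when any pixel's first
#'   harmonic was degenerate), `amplitude_flag` (TRUE when the pre-loss
#'   amplitude was zero and the relative change is undefined).
#' @export
seasonal_cycle_changes <- function(target, backgrounds, window,
                                   distances = NULL,
                                   weighting = c("mean", "idw")) {
  weighting <- match.arg(weighting)
  if (length(backgrounds) == 0L) stop("no valid backgrounds")
  one <- function(dec) {  # (amplitude change, phase change, amplitude before)
    ba <- seasonal_before_after(dec, window)
    c(harmonic_range(ba$after, 36L) - harmonic_range(ba$before, 36L),
      wrap_days(phase_day(ba$after) - phase_day(ba$before)),
      harmonic_range(ba$before, 36L))
  }
  o <- one(target)
  bg <- t(vapply(backgrounds, one, numeric(3L)))
  phase_flag <- anyNA(c(o[2], bg[, 2]))
  cb <- combine_backgrounds(bg[, 1:2, drop = FALSE], distances, weighting)
  dS_A <- o[1] - cb[1]
  dS_phi <- wrap_days(o[2] - cb[2])
  A0 <- o[3]
  amplitude_flag <- !is.finite(A0) || A0 <= 0
  dS_A_rel <- if (amplitude_flag) NA_real_ else 100 * dS_A / A0
  list(dS_A = dS_A, dS_A_rel = dS_A_rel, dS_phi = dS_phi,
       amplitude_before = A0, phase_flag = phase_flag,
       amplitude_flag = amplitude_flag)
}

PATTERN_LEVELS <- c("enhanced warming", "abrupt warming",
                    "attenuated warming", "attenuated cooling",
                    "abrupt cooling", "enhanced cooling", "insignificant")

#' Temporal-pattern classification
#'
#' Classifies the interaction of the abrupt and gradual responses. The
#' first sign comes from ΔT_1 against ±`thresholds[1]` (K), the second from
#' ΔT_slope against ±`thresholds[2]` (K/decade): (+ +) enhanced warming,
#' (+ ~) abrupt warming, (+ -) attenuated warming, (- +) attenuated
#' cooling, (- ~) abrupt cooling, (- -) enhanced cooling. An insignificant
#' first sign yields "insignificant" regardless of the slope; the raw signs
#' are returned alongside.
#'
#' @param dT1 Abrupt change(s), K.
#' @param dT_slope Gradual change(s), K/decade.
#' @param thresholds Margins `c(step, slope)`; defaults `(0.001, 0.002)`.
#' @return data.frame: `dT1`, `dT_slope`, `sign1`, `sign2`, `pattern`
#'   (factor over the seven labels).
#' @export
classify_pattern <- function(dT1, dT_slope,
                             thresholds = c(0.001, 0.002)) {
  stopifnot(length(dT1) == length(dT_slope),
            all(is.finite(dT1)), all(is.finite(dT_slope)))
  s1 <- ifelse(dT1 > thresholds[1], "+",
               ifelse(dT1 < -thresholds[1], "-", "~"))
  s2 <- ifelse(dT_slope > thresholds[2], "+",
               ifelse(dT_slope < -thresholds[2], "-", "~"))
  key <- paste(s1, s2)
  map <- c("+ +" = "enhanced warming", "+ ~" = "abrupt warming",
           "+ -" = "attenuated warming", "- +" = "attenuated cooling",
           "- ~" = "abrupt cooling", "- -" = "enhanced cooling")
  lab <- ifelse(s1 == "~", "insignificant", unname(map[key]))
  data.frame(dT1 = dT1, dT_slope = dT_slope, sign1 = s1, sign2 = s2,
             pattern = factor(lab, levels = PATTERN_LEVELS))
}

#' All response metrics for one paired sample
#'
#' Convenience wrapper computing the ΔT series, ΔT_1, ΔT_slope, monthly ΔS,
#' seasonal amplitude/phase changes and the pattern label in one call.
#'
#' @inheritParams delta_trend_series
#' @param thresholds Pattern margins passed to [classify_pattern()].
#' @return List of class `response_metrics`.
#' @export
response_metrics <- function(target, backgrounds, window, period,
                             distances = NULL,
                             weighting = c("mean", "idw"),
                             thresholds = c(0.001, 0.002)) {
  weighting <- match.arg(weighting)
  dT <- delta_trend_series(target, backgrounds, window, period, distances,
                           weighting)
  dT1 <- abrupt_change(dT, window)
  dTs <- gradual_slope(dT, window)
  dS <- delta_seasonal(target, backgrounds, window, distances, weighting)
  cyc <- seasonal_cycle_changes(target, backgrounds, window, distances,
                                weighting)
  pat <- classify_pattern(dT1, dTs, thresholds)
  structure(list(delta_t = dT, dT1 = dT1, dT_slope = dTs, delta_s = dS,
                 dS_A = cyc$dS_A, dS_A_rel = cyc$dS_A_rel,
                 dS_phi = cyc$dS_phi, flags = cyc[c("phase_flag",
                                                    "amplitude_flag")],
                 pattern = as.character(pat$pattern),
                 signs = c(pat$sign1, pat$sign2)),
            class = "response_metrics")
}
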