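#' @title Synthetic scene generation
#' @description Seeded generators producing raster-stack scenes with known
#'   ground truth: per-pixel 10-day series built as piecewise-linear trend +
#'   second-order harmonic seasonality + shared regional interannual anomaly
#'   + Gaussian noise, forest-loss events injected as a step and slope change
#'   in the trend plus amplitude/phase changes in the seasonal cycle, with
#'   coupled albedo and evapotranspiration steps.
#' @name synthetic
NULL

# Forest-loss driver classes and land-cover classes used throughout.
DRIVER_LEVELS <- c("cCRO", "URB", "shiftAG", "forestry", "fire")
LC_LEVELS <- c("cropland", "forest", "natural", "urban", "bare",
               "water", "ice")
SIGMA_SB <- 5.670374419e-8  # Stefan-Boltzmann, W m-2 K-4

#' Scene configuration
#'
#' Parameters of a synthetic scene. Defaults emulate a strong-response
#' forest-loss cohort at the observation scale of 1-km, 10-day composites:
#' abrupt warming of +0.30 K, a recovery slope of -0.14 K/decade, a seasonal
#' amplitude increase of +0.50 K and a phase advance of -1.8 days, with LST
#' noise of 0.5 K per composite.
#'
#' @param nrow,ncol Grid size (pixels).
#' @param pixel_size Pixel size in metres (planar, sinusoidal-like
#'   projection).
#' @param start_year,end_year Years covered by the stacks (inclusive; span
#'   must be at least 4 years).
#' @param lat_range Latitudes (degrees) spanned by the rows, `c(south,
#'   north)`; row 1 is the northernmost.
#' @param boreal_lat Latitude proxy above which pixels carry the boreal
#'   climate flag.
#' @param noise_sd LST observation noise per composite (K).
#' @param anomaly_sd Standard deviation of the shared regional interannual
#'   anomaly (K): yearly anomaly values interpolated smoothly across
#'   composites (mid-year knots) and added to every pixel's trend, so
#'   paired differencing removes it.
#' @param missing_frac Fraction of composites masked as missing, in `[0,
#'   1)`.
#' @param n_events Number of forest-loss events to inject.
#' @param loss_year_range Years (inclusive) in which losses may occur;
#'   `NULL` uses the 2005-2015 convention clipped to the scene span.
#' @param event_params Per-event truth distributions, a list of `c(mean,
#'   sd)` pairs: `step` (K), `slope` (K/decade), `amplitude` (K), `phase`
#'   (days, negative = advance), `albedo` (unitless step), `et` (mm/10 days
#'   step).
#' @param driver_mix Named sampling probabilities over
#'   `cCRO, URB, shiftAG, forestry, fire`.
#' @param couple_attribution If `TRUE`, albedo and ET steps are derived from
#'   the LST step through the energy-balance closed form using
#'   `attribution_shares`, so attribution recovery is testable; otherwise
#'   they are drawn from `event_params`.
#' @param attribution_shares Shares of the LST step explained by albedo and
#'   latent heat when `couple_attribution = TRUE` (remainder = sensible
#'   heat).
#' @param sw_down Pre-loss mean shortwave incident radiation (W m-2).
#' @param emissivity Broadband surface emissivity.
#' @param lambda_v Latent heat of vaporization (J kg-1).
#' @param albedo_noise_sd,et_noise_sd Observation noise of the albedo and ET
#'   stacks.
#' @param nonforest_frac Fraction of pixels assigned a non-forest land
#'   cover.
#' @param min_valid_candidates Minimum number of valid background candidates
#'   an event location must have at generation time.
#' @param seed Integer seed; scenes are bit-identical under the same seed.
#' @return A `scene_config` list.
#' @export
scene_config <- function(nrow = 110L, ncol = 110L, pixel_size = 1000,
                         start_year = 2003L, end_year = 2020L,
                         lat_range = c(45, 60), boreal_lat = 55,
                         noise_sd = 0.5, anomaly_sd = 0.3,
                         missing_frac = 0.05, n_events = 10L,
                         loss_year_range = NULL,
                         event_params = list(step = c(0.30, 0.05),
                                             slope = c(-0.14, 0.05),
                                             amplitude = c(0.50, 0.10),
                                             phase = c(-1.8, 0.5),
                                             albedo = c(0.02, 0.005),
                                             et = c(-1.5, 0.5)),
                         driver_mix = c(cCRO = 0.27, URB = 0.05,
                                        shiftAG = 0.22, forestry = 0.24,
                                        fire = 0.22),
                         couple_attribution = FALSE,
                         attribution_shares = c(albedo = 0.3, latent = 0.6),
                         sw_down = 200, emissivity = 0.97,
                         lambda_v = 2.45e6,
                         albedo_noise_sd = 0.005, et_noise_sd = 0.5,
                         nonforest_frac = 0.08,
                         min_valid_candidates = 30L, seed = 1L) {
  n_years <- end_year - start_year + 1L
  if (n_years < 4L) stop("years span must be at least 4")
  if (noise_sd < 0 || anomaly_sd < 0) stop("noise sd must be >= 0")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must be in [0, 1)")
  if (is.null(loss_year_range))
    loss_year_range <- c(max(2005L, start_year + 2L),
                         min(2015L, end_year - 1L))
  if (loss_year_range[1] < start_year + 2L ||
      loss_year_range[2] > end_year - 1L)
    stop("loss years must leave >= 2 pre-loss years and 1 post-loss year")
  if (is.null(names(driver_mix)) && length(driver_mix) == 5L)
    names(driver_mix) <- DRIVER_LEVELS
  driver_mix <- driver_mix[DRIVER_LEVELS]
  if (any(is.na(driver_mix)) || any(driver_mix < 0))
    stop("driver_mix must be non-negative over ", paste(DRIVER_LEVELS,
                                                        collapse = ", "))
  if (is.null(names(attribution_shares)) &&
      length(attribution_shares) == 2L)
    names(attribution_shares) <- c("albedo", "latent")
  out <- as.list(environment())
  out$n_years <- NULL
  structure(out, class = "scene_config")
}

#' Generate one pixel's synthetic 10-day series
#'
#' Builds trend + second-order harmonic seasonality + i.i.d. Gaussian noise,
#' with optional missing-data masking. The injected truth components are
#' attached as attributes `truth_trend` and `truth_seasonal`.
#'
#' @param trend Either `list(intercept =, slope =)` (slope in K per step) for
#'   a single segment, or a data.frame with columns `start_step`,
#'   `end_step`, `intercept`, `slope`.
#' @param harmonic Either a length-4 coefficient vector `c(gamma1, delta1,
#'   gamma2, delta2)` or a data.frame of segments with those columns plus
#'   `start_step`, `end_step`.
#' @param n_years,start_year Series span.
#' @param noise_sd Gaussian noise sd per composite.
#' @param missing_frac Fraction of steps masked at random.
#' @param ar1 Optional AR(1) coefficient for the noise (default 0, i.i.d.).
#' @param seed Optional seed.
#' @return A [ts10d] with truth attributes.
#' @export
make_pixel_series <- function(trend, harmonic, n_years, start_year = 2003L,
                              noise_sd = 0, missing_frac = 0, ar1 = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_years * 36L
  steps <- seq_len(n)
  trend_df <- as_segment_df(trend, n, c("intercept", "slope"))
  harm_df <- as_segment_df(harmonic, n, c("gamma1", "delta1",
                                          "gamma2", "delta2"))
  if (!all(is.finite(as.matrix(trend_df))) ||
      !all(is.finite(as.matrix(harm_df))))
    stop("non-finite trend/harmonic parameters")
  tr <- eval_trend(trend_df, steps)
  se <- eval_seasonal(harm_df, steps, 36L)
  noise <- if (noise_sd > 0) {
    e <- stats::rnorm(n, 0, noise_sd)
    if (ar1 != 0) as.numeric(stats::filter(e, ar1, method = "recursive"))
    else e
  } else rep(0, n)
  vals <- tr + se + noise
  if (missing_frac > 0) {
    vals[stats::runif(n) < missing_frac] <- NA_real_
  }
  out <- ts10d(vals, start_year)
  attr(out, "truth_trend") <- tr
  attr(out, "truth_seasonal") <- se
  out
}

as_segment_df <- function(x, n, coef_names) {
  if (is.data.frame(x)) {
    stopifnot(all(c("start_step", "end_step", coef_names) %in% names(x)))
    return(x)
  }
  x <- unlist(x, use.names = FALSE)
  if (length(x) != length(coef_names))
    stop("expected ", length(coef_names), " coefficients")
  df <- data.frame(start_step = 1L, end_step = n)
  df[coef_names] <- as.list(x)
  df
}

#' Inject a forest-loss event into a pixel's series bundle
#'
#' From the start of the loss year onward, offsets the LST trend by the step
#' and adds the slope change, rescales/shifts the seasonal harmonics to the
#' stated amplitude and phase changes, and applies the albedo and ET steps.
#' Truth attributes are updated alongside the values.
#'
#' @param bundle List with [ts10d] elements `lst`, and optionally `albedo`
#'   and `et`, each carrying truth attributes from [make_pixel_series()].
#' @param truth List/row with `loss_year`, `step` (K), `slope` (K/decade),
#'   `amplitude` (K), `phase` (days), `albedo`, `et` (stack steps).
#' @return The modified bundle; element `truth` echoes the record.
#' @export
inject_loss_event <- function(bundle, truth) {
  lst <- bundle$lst
  stopifnot(inherits(lst, "ts10d"))
  yr0 <- truth$loss_year
  last_year <- lst$start_year + lst$n_years - 1L
  if (yr0 < lst$start_year + 2L || yr0 > last_year - 1L)
    stop("loss year too close to series edges (need >= 2 pre-loss years)")
  tau0 <- (yr0 - lst$start_year) * 36L + 1L  # first step of the loss year
  n <- length(lst$values)
  post <- seq(tau0, n)
  years_since <- (post - tau0) / 36  # elapsed years since loss onset

  d_trend <- truth$step + (truth$slope / 10) * years_since
  seas_old <- attr(lst, "truth_seasonal")
  if (is.null(seas_old)) stop("bundle$lst lacks truth attributes")
  base_coef <- seasonal_coef_of(seas_old)
  new_coef <- shift_scale_harmonic(base_coef, truth$amplitude, truth$phase)
  seas_new_post <- as.numeric(harmonic_design(post, 36L) %*% new_coef)
  d_seas <- seas_new_post - seas_old[post]

  lst$values[post] <- lst$values[post] + d_trend + d_seas
  attr(lst, "truth_trend")[post] <- attr(lst, "truth_trend")[post] + d_trend
  attr(lst, "truth_seasonal")[post] <- seas_new_post
  bundle$lst <- lst

  for (nm in c("albedo", "et")) {
    if (is.null(bundle[[nm]])) next
    s <- bundle[[nm]]
    d <- if (nm == "albedo") truth$albedo else truth$et
    s$values[post] <- s$values[post] + d
    attr(s, "truth_trend")[post] <- attr(s, "truth_trend")[post] + d
    bundle[[nm]] <- s
  }
  bundle$truth <- truth
  bundle
}

# Recover (gamma1, delta1, gamma2, delta2) from one cycle of a noiseless
# seasonal series by projection (harmonics are orthogonal over 36 steps).
seasonal_coef_of <- function(seas) {
  t1 <- seq_len(36L)
  X <- harmonic_design(t1, 36L)
  as.numeric(stats::lm.fit(X, seas[t1])$coefficients)
}

# Scale a second-order harmonic so its range grows by d_amp (K) and delay it
# by d_phase days (negative = advance).
shift_scale_harmonic <- function(coef, d_amp, d_phase) {
  r <- harmonic_range(coef, 36L)
  f <- if (r > 0) (r + d_amp) / r else 1
  d <- d_phase / DAYS_PER_STEP  # steps
  out <- numeric(4L)
  for (h in 1:2) {
    g <- coef[2L * h - 1L]; dl <- coef[2L * h]
    cs <- cos(2 * pi * h * d / 36); sn <- sin(2 * pi * h * d / 36)
    out[2L * h - 1L] <- f * (g * cs + dl * sn)
    out[2L * h] <- f * (-g * sn + dl * cs)
  }
  out
}

#' Generate a synthetic scene
#'
#' Builds the full raster bundle: LST, albedo and ET stacks, static rasters
#' (elevation, land cover, forest cover 2000, loss year/percentage/driver,
#' latitude, region class) and the truth table. All pixels share one
#' regional interannual anomaly (constant within each year) so paired
#' differencing can remove it. Loss events are placed only where the 25-50
#' km background annulus holds at least `min_valid_candidates` valid
#' stable-forest candidates and more than 5% of the annulus is valid.
#'
#' @param config A [scene_config()].
#' @return An object of class `lst_scene`: stacks are arrays
#'   `[step, row, col]`; statics are `nrow x ncol` matrices; `truth` is a
#'   data.frame (one row per injected event).
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cf <- config
  set.seed(cf$seed)
  nr <- cf$nrow; nc <- cf$ncol
  npix <- nr * nc
  n_years <- cf$end_year - cf$start_year + 1L
  n <- n_years * 36L
  extent <- min(nr, nc) * cf$pixel_size
  if (extent < 2 * 25000 + cf$pixel_size)
    stop("grid too small to host the 25-50 km background ring at ",
         cf$pixel_size, " m pixels")

  lat_row <- seq(cf$lat_range[2], cf$lat_range[1], length.out = nr)
  lat <- matrix(rep(lat_row, nc), nr, nc)
  elevation <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    elevation[, j] <- 300 + 80 * sin(2 * pi * seq_len(nr) / nr) *
      cos(2 * pi * j / nc)
  }
  elevation <- elevation + matrix(stats::rnorm(npix, 0, 10), nr, nc)
  landcover <- matrix("forest", nr, nc)
  nonforest <- sample(npix, round(cf$nonforest_frac * npix))
  landcover[nonforest] <- sample(setdiff(LC_LEVELS, "forest"),
                                 length(nonforest), replace = TRUE)
  cover2000 <- matrix(stats::runif(npix, 80, 100), nr, nc)
  cover2000[landcover != "forest"] <- stats::runif(sum(landcover != "forest"),
                                                   0, 10)

  # base per-pixel model, driven by latitude
  mean_lst_row <- 305 - 0.55 * abs(lat_row)
  amp1_row <- 0.30 * abs(lat_row)
  slope_step <- 0.02 / 36  # mild background climate trend, K per step
  steps <- seq_len(n)
  peak_step <- ifelse(lat_row >= 0, 20, 2)
  w <- 2 * pi / 36
  seas_row <- matrix(0, n, nr)
  base_coef_row <- matrix(0, nr, 4L)
  for (r in seq_len(nr)) {
    a1 <- amp1_row[r]
    cf4 <- c(a1 * sin(w * peak_step[r]), a1 * cos(w * peak_step[r]),
             0.05 * a1, -0.03 * a1)
    base_coef_row[r, ] <- cf4
    seas_row[, r] <- harmonic_design(steps, 36L) %*% cf4
  }
  # shared interannual anomaly: AR(1) across years (persistence 0.8,
  # marginal sd = anomaly_sd) as regional climate anomalies are strongly
  # autocorrelated; smooth mid-year interpolation avoids artificial
  # year-boundary jumps
  rho <- 0.8
  innov <- stats::rnorm(n_years, 0, cf$anomaly_sd * sqrt(1 - rho^2))
  anomaly_year <- as.numeric(stats::filter(innov, rho,
                                           method = "recursive"))
  anomaly <- stats::approx(x = (seq_len(n_years) - 0.5) * 36,
                           y = anomaly_year, xout = steps - 0.5,
                           rule = 2)$y

  build_stack <- function(base_mat, noise_sd, with_anomaly) {
    x <- base_mat + matrix(stats::rnorm(n * npix, 0, noise_sd), n, npix)
    if (with_anomaly) x <- x + anomaly
    array(x, dim = c(n, nr, nc))
  }
  # base matrices (n x npix), pixel order = column-major (row fastest)
  row_of <- rep(seq_len(nr), nc)
  base_lst <- matrix(0, n, npix)
  for (r in seq_len(nr)) {
    cols <- which(row_of == r)
    base_lst[, cols] <- mean_lst_row[r] + slope_step * steps + seas_row[, r]
  }
  lst <- build_stack(base_lst, cf$noise_sd, with_anomaly = TRUE)
  alb_seas <- 0.03 * seas_row / max(abs(seas_row))  # winter-bright albedo
  base_alb <- matrix(0.12, n, npix)
  for (r in seq_len(nr)) base_alb[, cols <- which(row_of == r)] <-
      0.12 - alb_seas[, r]
  albedo <- build_stack(base_alb, cf$albedo_noise_sd, with_anomaly = FALSE)
  base_et <- matrix(0, n, npix)
  for (r in seq_len(nr)) base_et[, cols <- which(row_of == r)] <-
      8 + 6 * seas_row[, r] / max(abs(seas_row))
  et <- build_stack(base_et, cf$et_noise_sd, with_anomaly = FALSE)
  rm(base_lst, base_alb, base_et)

  if (cf$missing_frac > 0) {
    lst[stats::runif(length(lst)) < cf$missing_frac] <- NA_real_
  }

  loss_year <- matrix(NA_integer_, nr, nc)
  loss_pct <- matrix(0, nr, nc)
  driver <- matrix(NA_character_, nr, nc)

  # event placement with background-ring support
  truth <- data.frame()
  if (cf$n_events > 0L) {
    forest_idx <- which(landcover == "forest")
    placed <- integer(0)
    tries <- 0L
    while (length(placed) < cf$n_events && tries < 200L * cf$n_events) {
      tries <- tries + 1L
      cand <- sample(forest_idx, 1L)
      if (cand %in% placed) next
      r0 <- (cand - 1L) %% nr + 1L
      c0 <- (cand - 1L) %/% nr + 1L
      ring <- annulus_indices(nr, nc, r0, c0, cf$pixel_size)
      if (length(ring) == 0L) next
      ok <- landcover[ring] == "forest" & !(ring %in% placed) &
        abs(elevation[ring] - elevation[cand]) < 100
      if (sum(ok) >= cf$min_valid_candidates &&
          sum(ok) > 0.05 * length(ring)) placed <- c(placed, cand)
    }
    if (length(placed) < cf$n_events)
      stop("could not place ", cf$n_events, " events with valid rings")

    ep <- cf$event_params
    draw <- function(p, k) stats::rnorm(k, p[1], p[2])
    k <- cf$n_events
    sens_row <- 1 / (4 * cf$emissivity * SIGMA_SB * mean_lst_row^3)
    truth <- data.frame(
      event_id = seq_len(k),
      row = (placed - 1L) %% nr + 1L,
      col = (placed - 1L) %/% nr + 1L,
      loss_year = sample(seq(cf$loss_year_range[1], cf$loss_year_range[2]),
                         k, replace = TRUE),
      loss_pct = stats::runif(k, 30, 100),
      driver = sample(DRIVER_LEVELS, k, replace = TRUE,
                      prob = cf$driver_mix),
      step = draw(ep$step, k), slope = draw(ep$slope, k),
      amplitude = draw(ep$amplitude, k), phase = draw(ep$phase, k),
      albedo = draw(ep$albedo, k), et = draw(ep$et, k),
      stringsAsFactors = FALSE)
    truth$x <- (truth$col - 0.5) * cf$pixel_size
    truth$y <- (truth$row - 0.5) * cf$pixel_size
    truth$lat <- lat_row[truth$row]
    sens_ev <- sens_row[truth$row]
    if (cf$couple_attribution) {
      sh <- cf$attribution_shares
      truth$albedo <- -(sh[["albedo"]] * truth$step) /
        (sens_ev * cf$sw_down)
      d_le <- -(sh[["latent"]] * truth$step) / sens_ev
      truth$et <- d_le * 864000 / cf$lambda_v
    }
    truth$dT_alpha <- sens_ev * (-cf$sw_down * truth$albedo)
    truth$dT_le <- sens_ev * (-(truth$et * cf$lambda_v / 864000))

    for (i in seq_len(k)) {
      r0 <- truth$row[i]; c0 <- truth$col[i]
      tau0 <- (truth$loss_year[i] - cf$start_year) * 36L + 1L
      post <- seq(tau0, n)
      yrs <- (post - tau0) / 36
      d_trend <- truth$step[i] + (truth$slope[i] / 10) * yrs
      new_coef <- shift_scale_harmonic(base_coef_row[r0, ],
                                       truth$amplitude[i], truth$phase[i])
      d_seas <- as.numeric(harmonic_design(post, 36L) %*% new_coef) -
        seas_row[post, r0]
      lst[post, r0, c0] <- lst[post, r0, c0] + d_trend + d_seas
      albedo[post, r0, c0] <- albedo[post, r0, c0] + truth$albedo[i]
      et[post, r0, c0] <- et[post, r0, c0] + truth$et[i]
      loss_year[r0, c0] <- truth$loss_year[i]
      loss_pct[r0, c0] <- truth$loss_pct[i]
      driver[r0, c0] <- truth$driver[i]
    }
  }

  boreal <- lat >= cf$boreal_lat
  region <- matrix(assign_region(as.numeric(lat), as.logical(boreal)),
                   nr, nc)
  structure(
    list(config = cf, lst = lst, albedo = albedo, et = et,
         elevation = elevation, landcover = landcover,
         cover2000 = cover2000, loss_year = loss_year,
         loss_pct = loss_pct, driver = driver, lat = lat,
         boreal = boreal, region = region, truth = truth,
         base_seasonal_coef = base_coef_row,
         anomaly_year = anomaly_year),
    class = "lst_scene")
}

#' @export
print.lst_scene <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<lst_scene> %dx%d px, %d-%d, %d events\n", cf$nrow, cf$ncol,
              cf$start_year, cf$end_year, nrow(x$truth)))
  invisible(x)
}

# Pixel indices (column-major) within the 25-50 km annulus of (r0, c0).
annulus_indices <- function(nr, nc, r0, c0, pixel_size,
                            inner = 25000, outer = 50000) {
  dr <- ceiling(outer / pixel_size)
  rows <- max(1L, r0 - dr):min(nr, r0 + dr)
  cols <- max(1L, c0 - dr):min(nc, c0 + dr)
  g <- expand.grid(row = rows, col = cols)
  d <- pixel_size * sqrt((g$row - r0)^2 + (g$col - c0)^2)
  keep <- d >= inner & d <= outer
  (g$col[keep] - 1L) * nr + g$row[keep]
}

#' Extract one pixel's series from a scene
#'
#' @param scene An [make_scene()] scene.
#' @param row,col Pixel location.
#' @param var One of `"lst"`, `"albedo"`, `"et"`.
#' @return A [ts10d].
#' @export
scene_series <- function(scene, row, col, var = c("lst", "albedo", "et")) {
  var <- match.arg(var)
  ts10d(scene[[var]][, row, col], scene$config$start_year)
}
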