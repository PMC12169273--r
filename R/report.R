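#' @title Regional aggregation and end-to-end driver
#' @description Climate-region assignment, latitudinal binning, zonal means
#'   with confidence intervals and t-tests, and the end-to-end pipeline
#'   over a synthetic scene.
#' @name report
NULL

REGION_LEVELS <- c("SM", "LL", "NM", "boreal")

#' Assign climate regions
#'
#' Southern mid-latitudes (SM) span 60S-20S, low latitudes (LL) 20S-20N,
#' and latitudes above 20N split into boreal (flagged pixels) and northern
#' mid-latitudes (NM). Latitudes below 60S fall outside the study domain
#' and return `NA`.
#'
#' @param lat Latitude in degrees, |lat| <= 90.
#' @param boreal Logical boreal-climate flag (recycled).
#' @return Character vector over `SM`, `LL`, `NM`, `boreal`.
#' @export
assign_region <- function(lat, boreal = FALSE) {
  stopifnot(all(abs(lat) <= 90))
  boreal <- rep_len(boreal, length(lat))
  out <- rep(NA_character_, length(lat))
  out[lat >= -60 & lat < -20] <- "SM"
  out[lat >= -20 & lat <= 20] <- "LL"
  north <- lat > 20
  out[north] <- ifelse(boreal[north], "boreal", "NM")
  out
}

#' 5-degree latitude bins
#'
#' Half-open bins `[lower, upper)` from 60S to 80N.
#'
#' @param lat Latitude in degrees.
#' @param width Bin width in degrees (default 5).
#' @return Factor of bin labels; the bin centre is attached as
#'   `attr(, "centers")`.
#' @export
lat_bins <- function(lat, width = 5) {
  edges <- seq(-60, 80, by = width)
  f <- cut(lat, edges, right = FALSE)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  attr(f, "centers") <- centers[as.integer(f)]
  f
}

#' Zonal summary of per-event metric values
#'
#' Group means with Student-t 95% confidence intervals and a one-sample
#' t-test against zero per group. Singleton groups report the mean with an
#' undefined interval and are flagged.
#'
#' @param values Numeric per-event metric values.
#' @param groups Grouping vector (region, latitude bin, driver, ...).
#' @param metric Metric name carried into the output.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame: `group`, `metric`, `n`, `mean`, `ci_half`
#'   (half-width), `t`, `p`, `significant` (p < 0.05), `flag`.
#' @export
zonal_summary <- function(values, groups, metric = "metric",
                          conf_level = 0.95) {
  keep <- !is.na(values) & !is.na(groups)
  sp <- split(values[keep], droplevels(factor(groups[keep])))
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    n <- length(v)
    if (n >= 2L && stats::sd(v) > 0) {
      tt <- stats::t.test(v, mu = 0, conf.level = conf_level)
      data.frame(group = g, metric = metric, n = n, mean = mean(v),
                 ci_half = unname(diff(tt$conf.int)) / 2,
                 t = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < 0.05, flag = NA_character_)
    } else if (n >= 2L) {
      data.frame(group = g, metric = metric, n = n, mean = mean(v),
                 ci_half = 0, t = NaN, p = as.numeric(mean(v) != 0),
                 significant = mean(v) != 0, flag = "zero variance")
    } else {
      data.frame(group = g, metric = metric, n = n, mean = mean(v),
                 ci_half = NA_real_, t = NA_real_, p = NA_real_,
                 significant = NA, flag = "singleton group")
    }
  })
  do.call(rbind, rows)
}

#' Analyse a scene end to end
#'
#' For every injected event: decomposes the target LST series (with
#' bootstrap break-date intervals), matches the loss to detected abrupt
#' changes, derives the loss window and study period, selects and samples
#' background controls, computes response metrics, and (optionally)
#' energy-balance attribution from the albedo and ET stacks. Background
#' decompositions are cached across events.
#'
#' @param scene A [make_scene()] scene.
#' @param weighting Background combination, `"mean"` or `"idw"`.
#' @param max_backgrounds Backgrounds sampled per event (default 20).
#' @param bootstrap_reps Bootstrap replicates for target break intervals.
#' @param thresholds Pattern-classification margins.
#' @param attribution Compute energy-balance attribution (default TRUE).
#' @param pre_years Pre-window baseline depth for [study_period()].
#' @return List of class `lst_analysis`: `metrics` (one row per analysed
#'   event), `excluded` (event id + reason), `delta_t` (long ΔT
#'   trajectories), `delta_s` (long monthly ΔS), and `attribution` (long
#'   yearly terms) when requested.
#' @export
analyze_scene <- function(scene, weighting = c("mean", "idw"),
                          max_backgrounds = 20L, bootstrap_reps = 100L,
                          thresholds = c(0.001, 0.002),
                          attribution = TRUE, pre_years = 2L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(scene, "lst_scene"))
  cf <- scene$config
  px <- scene_pixels(scene)
  cache <- new.env(parent = emptyenv())
  full_design <- NULL
  dec_of <- function(row, col, var) {
    key <- paste(var, row, col)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- scene_series(scene, row, col, var)
    des <- NULL
    if (!anyNA(s$values)) {  # complete series share one design cache
      if (is.null(full_design))
        full_design <<- seg_design(seq_along(s$values))
      des <- full_design
    }
    d <- fit_decomposition(s, bootstrap_reps = 0L, .design = des)
    cache[[key]] <- d
    d
  }
  metrics <- list(); excluded <- list(); traj <- list(); seas <- list()
  attr_rows <- list()
  for (i in seq_len(nrow(scene$truth))) {
    ev <- scene$truth[i, ]
    res <- analyze_event(scene, ev, px, dec_of, weighting,
                         max_backgrounds, bootstrap_reps, thresholds,
                         attribution, pre_years)
    if (!is.null(res$reason)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(event_id = ev$event_id, reason = res$reason)
      next
    }
    metrics[[length(metrics) + 1L]] <- res$row
    traj[[length(traj) + 1L]] <- cbind(event_id = ev$event_id,
                                       res$rm$delta_t)
    seas[[length(seas) + 1L]] <- cbind(event_id = ev$event_id,
                                       res$rm$delta_s)
    if (!is.null(res$att)) {
      a <- res$att
      attr_rows[[length(attr_rows) + 1L]] <-
        data.frame(event_id = ev$event_id, year = a$year, dT = a$dT,
                   dT_alpha = a$dT_alpha, dT_le = a$dT_le, dT_h = a$dT_h)
    }
  }
  structure(
    list(metrics = do.call(rbind, metrics),
         excluded = if (length(excluded)) do.call(rbind, excluded)
                    else data.frame(event_id = integer(0),
                                    reason = character(0)),
         delta_t = do.call(rbind, traj),
         delta_s = do.call(rbind, seas),
         attribution = if (length(attr_rows)) do.call(rbind, attr_rows),
         weighting = weighting),
    class = "lst_analysis")
}

analyze_event <- function(scene, ev, px, dec_of, weighting,
                          max_backgrounds, bootstrap_reps, thresholds,
                          attribution, pre_years) {
  cf <- scene$config
  seed_i <- (cf$seed %% 100000L) * 1000L + ev$event_id
  target_dec <- fit_decomposition(
    scene_series(scene, ev$row, ev$col, "lst"),
    bootstrap_reps = bootstrap_reps, seed = seed_i)
  matched <- match_loss_to_breaks(ev, target_dec)
  if (nrow(matched) == 0L) return(list(reason = "no matched break"))
  win <- loss_window(ev, matched)
  if (win$start - pre_years < cf$start_year)
    return(list(reason = "study period before series start"))
  per <- study_period(win, target_dec$breakpoints, cf$start_year,
                      cf$end_year, pre_years)
  if (!per$usable) return(list(reason = per$reason))
  if (per$end < win$end + 3L) return(list(reason = "post-loss span < 3 years"))
  tgt <- list(x = ev$x, y = ev$y,
              elevation = scene$elevation[ev$row, ev$col],
              loss_pct = ev$loss_pct)
  sel <- select_background(tgt, px)
  if (!sel$accepted) return(list(reason = sel$reason))
  bg <- sel$background
  set.seed(seed_i + 500000L)
  take <- sample(nrow(bg), min(max_backgrounds, nrow(bg)))
  bg <- bg[take, , drop = FALSE]
  bg_dec <- lapply(seq_len(nrow(bg)),
                   function(j) dec_of(bg$row[j], bg$col[j], "lst"))
  rm <- response_metrics(target_dec, bg_dec, win, per,
                         distances = bg$distance, weighting = weighting,
                         thresholds = thresholds)
  att <- NULL; dT1_alpha <- dT1_le <- dT1_h <- NA_real_
  if (attribution) {
    base_steps <- ts10d_year_steps(target_dec$series, cf$start_year)
    lst_base <- mean(scene$lst[base_steps, ev$row, ev$col], na.rm = TRUE)
    inp <- eb_inputs(cf$emissivity, lst_base, cf$sw_down, cf$lambda_v)
    alb_t <- dec_of(ev$row, ev$col, "albedo")
    et_t <- dec_of(ev$row, ev$col, "et")
    alb_b <- lapply(seq_len(nrow(bg)),
                    function(j) dec_of(bg$row[j], bg$col[j], "albedo"))
    et_b <- lapply(seq_len(nrow(bg)),
                   function(j) dec_of(bg$row[j], bg$col[j], "et"))
    att <- attribute(rm, alb_t, alb_b, et_t, et_b, win, per, inp,
                     distances = bg$distance, weighting = weighting)
    i1 <- match(win$end + 1L, att$year)
    dT1_alpha <- att$dT_alpha[i1]; dT1_le <- att$dT_le[i1]
    dT1_h <- att$dT_h[i1]
  }
  row <- data.frame(
    event_id = ev$event_id, row = ev$row, col = ev$col, lat = ev$lat,
    region = scene$region[ev$row, ev$col], driver = ev$driver,
    loss_year = ev$loss_year, loss_pct = ev$loss_pct,
    window_start = win$start, window_end = win$end,
    period_start = per$start, period_end = per$end,
    n_annulus = sel$n_annulus, n_valid = sel$n_valid,
    n_bg = nrow(bg),
    dT1 = rm$dT1, dT_slope = rm$dT_slope, dS_A = rm$dS_A,
    dS_A_rel = rm$dS_A_rel, dS_phi = rm$dS_phi,
    pattern = rm$pattern,
    dT1_alpha = dT1_alpha, dT1_le = dT1_le, dT1_h = dT1_h,
    stringsAsFactors = FALSE)
  list(row = row, rm = rm, att = att)
}

#' Run the full pipeline on a scene configuration
#'
#' Generates the scene, analyses every event, aggregates zonal summaries
#' (per region and per driver) and cohort trajectories, and optionally
#' writes `metrics.csv`, `attribution.csv`, `zonal_summary.csv`,
#' `trajectories.csv` and a `run.json` log to `out_dir`. Deterministic
#' under the configuration seed.
#'
#' @param config A [scene_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param ... Passed to [analyze_scene()].
#' @return List of class `lst_run`: the analysis plus `zonal`, `patterns`,
#'   `trajectories`, `truth` and the run `log`.
#' @export
run_all <- function(config, out_dir = NULL, ...) {
  scene <- make_scene(config)
  an <- analyze_scene(scene, ...)
  m <- an$metrics
  if (is.null(m) || nrow(m) == 0L) stop("no events analysed")
  zonal <- rbind(
    zonal_summary(m$dT1, m$region, "dT1"),
    zonal_summary(m$dT_slope, m$region, "dT_slope"),
    zonal_summary(m$dS_A, m$region, "dS_A"),
    zonal_summary(m$dS_phi, m$region, "dS_phi"),
    zonal_summary(m$dT1, m$driver, "dT1_by_driver"),
    zonal_summary(m$dT_slope, m$driver, "dT_slope_by_driver"))
  patterns <- as.data.frame(table(pattern = m$pattern),
                            responseName = "n")
  patterns$share <- patterns$n / sum(patterns$n)
  tr <- an$delta_t
  post <- tr[tr$years_since_loss >= 1L, , drop = FALSE]
  trajectories <- zonal_summary(post$dT, post$years_since_loss, "dT")
  names(trajectories)[names(trajectories) == "group"] <- "years_since_loss"
  log <- list(seed = config$seed, n_events = config$n_events,
              n_analysed = nrow(m), n_excluded = nrow(an$excluded),
              weighting = an$weighting,
              package = as.character(utils::packageVersion("lstdyn")),
              config = config[c("nrow", "ncol", "start_year", "end_year",
                                "noise_sd", "anomaly_sd", "missing_frac")])
  out <- structure(c(an, list(zonal = zonal, patterns = patterns,
                              trajectories = trajectories,
                              truth = scene$truth, log = log)),
                   class = "lst_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.lst_run <- function(x, ...) {
  cat(sprintf("<lst_run> %d events analysed (%d excluded)\n",
              nrow(x$metrics), nrow(x$excluded)))
  cat(sprintf("  mean dT1 = %+.3f K, dT_slope = %+.3f K/decade\n",
              mean(x$metrics$dT1), mean(x$metrics$dT_slope)))
  cat(sprintf("  mean dS_A = %+.3f K, dS_phi = %+.2f days\n",
              mean(x$metrics$dS_A), mean(x$metrics$dS_phi, na.rm = TRUE)))
  dom <- x$patterns$pattern[which.max(x$patterns$n)]
  cat(sprintf("  dominant pattern: %s\n", dom))
  invisible(x)
}
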