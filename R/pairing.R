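#' @title Paired-pixel extraction
#' @description Matching forest-loss events to detected LST breaks, loss
#'   window and study period definition, and background control selection in
#'   the 25-50 km annulus.
#' @name pairing
NULL

#' Aggregate high-resolution forest maps to the analysis grid
#'
#' Block-aggregates a high-resolution loss mask, year-2000 forest-cover
#' fractions, and a loss-driver map onto coarse cells: loss percentage is
#' the block mean of (loss indicator x cover fraction) x 100, cover
#' percentage the block mean x 100, and the driver the mode over lost
#' subpixels (ties broken by the fixed class order cCRO < URB < shiftAG <
#' forestry < fire).
#'
#' @param loss_mask 0/1 matrix of lost subpixels.
#' @param cover2000 Matrix of forest-cover fractions in `[0, 1]`.
#' @param driver_map Character matrix of driver classes (`NA` where not
#'   lost).
#' @param block Aggregation factor; high-res dims must be exact multiples.
#' @return List of coarse matrices `loss_pct`, `cover_pct`, `driver`
#'   (`NA` where no subpixel was lost).
#' @export
aggregate_forest_maps <- function(loss_mask, cover2000, driver_map, block) {
  d <- dim(loss_mask)
  if (!all(d == dim(cover2000)) || !all(d == dim(driver_map)))
    stop("input grids must share dimensions")
  if (any(d %% block != 0L)) stop("block size does not tile the grid")
  nr <- d[1] %/% block
  nc <- d[2] %/% block
  loss_pct <- cover_pct <- matrix(0, nr, nc)
  driver <- matrix(NA_character_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- ((i - 1L) * block + 1L):(i * block)
      cj <- ((j - 1L) * block + 1L):(j * block)
      lm <- loss_mask[ri, cj]
      cv <- cover2000[ri, cj]
      loss_pct[i, j] <- mean(lm * cv) * 100
      cover_pct[i, j] <- mean(cv) * 100
      lost <- lm == 1
      if (any(lost)) {
        dv <- factor(driver_map[ri, cj][lost], levels = DRIVER_LEVELS)
        cnt <- table(dv)
        driver[i, j] <- DRIVER_LEVELS[which.max(cnt)]
      }
    }
  }
  list(loss_pct = loss_pct, cover_pct = cover_pct, driver = driver)
}

#' Pixel geography table for a scene
#'
#' One row per pixel with projected coordinates, latitude, elevation, land
#' cover, forest cover and forest-change percentage (loss + gain over the
#' record; the synthetic generator injects no gain).
#'
#' @param scene An [make_scene()] scene.
#' @return data.frame keyed by `row`, `col`.
#' @export
scene_pixels <- function(scene) {
  cf <- scene$config
  nr <- cf$nrow; nc <- cf$ncol
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  data.frame(
    row = g$row, col = g$col,
    x = (g$col - 0.5) * cf$pixel_size,
    y = (g$row - 0.5) * cf$pixel_size,
    lat = scene$lat[cbind(g$row, g$col)],
    elevation = scene$elevation[cbind(g$row, g$col)],
    landcover = scene$landcover[cbind(g$row, g$col)],
    cover_pct = scene$cover2000[cbind(g$row, g$col)],
    change_pct = scene$loss_pct[cbind(g$row, g$col)],
    stringsAsFactors = FALSE)
}

#' Match a forest-loss event to detected abrupt changes
#'
#' A detected break matches the loss event iff (a) the loss year lies within
#' the break's confidence interval and (b) the break year differs from the
#' loss year by at most two years. Both trend and seasonal breaks are
#' considered.
#'
#' @param event List/row with `loss_year`.
#' @param result An [fit_decomposition()] result for the event pixel.
#' @return The matching rows of `result$breakpoints` (possibly 0 rows).
#' @export
match_loss_to_breaks <- function(event, result) {
  stopifnot(inherits(result, "lst_decomp"))
  b <- result$breakpoints
  if (nrow(b) == 0L) return(b)
  hit <- event$loss_year >= b$ci_lo_year & event$loss_year <= b$ci_hi_year &
    abs(b$year - event$loss_year) <= 2L
  b[hit, , drop = FALSE]
}

#' Loss window of a matched event
#'
#' The window spans the union of the loss year and the years of all matched
#' abrupt changes.
#'
#' @param event List/row with `loss_year`.
#' @param matched Matched break rows from [match_loss_to_breaks()].
#' @return List with `start` and `end` years.
#' @export
loss_window <- function(event, matched) {
  if (is.null(matched) || nrow(matched) == 0L)
    stop("loss_window requires at least one matched break")
  yrs <- c(event$loss_year, matched$year)
  list(start = min(yrs), end = max(yrs))
}

#' Study period of a paired sample
#'
#' The analysed span starts `pre_years` before the loss window (default 2,
#' guaranteeing two pre-loss years) and ends the year before the confidence
#' interval of the next detected abrupt change begins, or at the series end
#' when no later break exists.
#'
#' @param window A [loss_window()].
#' @param breakpoints The full `breakpoints` table of the pixel's
#'   decomposition.
#' @param series_start,series_end First/last calendar year of the series.
#' @param pre_years Years of pre-window baseline (2 by default; 1
#'   reproduces a literal one-year-before reading).
#' @return List with `start`, `end`, `usable` flag and `reason` when
#'   unusable.
#' @export
study_period <- function(window, breakpoints, series_start, series_end,
                         pre_years = 2L) {
  start <- window$start - pre_years
  if (start < series_start) stop("study period starts before the series")
  later <- breakpoints[breakpoints$year > window$end, , drop = FALSE]
  end <- if (nrow(later)) min(later$ci_lo_year) - 1L else series_end
  end <- min(end, series_end)
  if (end <= window$end)
    return(list(start = start, end = end, usable = FALSE,
                reason = "empty post-loss span"))
  list(start = start, end = end, usable = TRUE, reason = NA_character_)
}

#' Select valid background control pixels
#'
#' Valid backgrounds lie within 25-50 km (inclusive) of the target, keep
#' stable forest cover with a forest-change percentage below min(2%, P),
#' and differ in elevation by less than 100 m. The sample is retained only
#' when valid pixels exceed 5% of all annulus candidates.
#'
#' @param target List/row with `x`, `y`, `elevation` and `loss_pct` (P, %).
#' @param candidates Pixel table (e.g. [scene_pixels()]) covering the
#'   annulus; the target itself is ignored if present.
#' @param inner,outer Annulus radii in metres (inclusive bounds).
#' @param max_elev_diff Elevation tolerance in metres (strict).
#' @param stable_thresh Forest-change ceiling in percent (2).
#' @param min_valid_frac Minimum valid fraction of the annulus (0.05,
#'   strict).
#' @return List: `background` (valid rows with `distance` in m), `n_annulus`,
#'   `n_valid`, `valid_frac`, `accepted`, `reason`.
#' @export
select_background <- function(target, candidates, inner = 25000,
                              outer = 50000, max_elev_diff = 100,
                              stable_thresh = 2, min_valid_frac = 0.05) {
  d <- sqrt((candidates$x - target$x)^2 + (candidates$y - target$y)^2)
  in_ring <- d >= inner & d <= outer
  ann <- candidates[in_ring, , drop = FALSE]
  ann$distance <- d[in_ring]
  n_ann <- nrow(ann)
  if (n_ann == 0L)
    return(list(background = ann, n_annulus = 0L, n_valid = 0L,
                valid_frac = NA_real_, accepted = FALSE,
                reason = "empty annulus"))
  thr <- min(stable_thresh, target$loss_pct)
  ok <- ann$landcover == "forest" &
    ann$change_pct < thr &
    abs(ann$elevation - target$elevation) < max_elev_diff
  bg <- ann[ok, , drop = FALSE]
  frac <- nrow(bg) / n_ann
  accepted <- frac > min_valid_frac
  list(background = bg, n_annulus = n_ann, n_valid = nrow(bg),
       valid_frac = frac, accepted = accepted,
       reason = if (accepted) NA_character_ else "valid fraction <= 5%")
}
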