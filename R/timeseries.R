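#' 10-day composite time series for one pixel
#'
#' Container for a single pixel's 10-day composite series (land surface
#' temperature in K, albedo, or evapotranspiration in mm/10 days). The year is
#' divided into 36 composite steps (3 per calendar month); missing
#' observations are encoded as `NA`.
#'
#' @param values Numeric vector of observations; length must be a whole
#'   number of years times 36. `NA` marks missing composites.
#' @param start_year First calendar year covered by the series.
#' @param period Steps per year; fixed at 36 for 10-day composites.
#' @return An object of class `ts10d` with fields `values`, `start_year`,
#'   `period`, `n_years`.
#' @examples
#' x <- ts10d(rnorm(36 * 5, 290), start_year = 2003)
#' ts10d_years(x)[1:3]
#' @export
ts10d <- function(values, start_year, period = 36L) {
  values <- as.numeric(values)
  if (period != 36L) stop("period must be 36 (10-day composites)")
  n <- length(values)
  if (n == 0L || n %% period != 0L)
    stop("length(values) must be a positive multiple of ", period)
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite or NA")
  structure(
    list(values = values, start_year = as.integer(start_year),
         period = as.integer(period), n_years = n %/% period),
    class = "ts10d"
  )
}

#' @export
print.ts10d <- function(x, ...) {
  cat(sprintf("<ts10d> %d years from %d (%d steps, %d missing)\n",
              x$n_years, x$start_year, length(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.ts10d <- function(x) length(x$values)

#' Calendar year of each composite step
#'
#' @param x A [ts10d] series.
#' @return Integer vector, one year per step.
#' @export
ts10d_years <- function(x) {
  x$start_year + (seq_along(x$values) - 1L) %/% x$period
}

#' Continuous time of each composite step
#'
#' Mid-composite convention: step s of a year maps to
#' `year + (s - 0.5) / 36`.
#'
#' @param x A [ts10d] series.
#' @return Numeric vector of decimal years.
#' @export
ts10d_time <- function(x) {
  s <- (seq_along(x$values) - 1L) %% x$period + 1L
  ts10d_years(x) + (s - 0.5) / x$period
}

#' Steps belonging to a calendar year
#' @param x A [ts10d] series.
#' @param year Calendar year inside the span.
#' @return Integer vector of 36 step indices.
#' @export
ts10d_year_steps <- function(x, year) {
  if (year < x$start_year || year > x$start_year + x$n_years - 1L)
    stop("year ", year, " outside series span")
  offset <- (year - x$start_year) * x$period
  offset + seq_len(x$period)
}

# Days per composite step (365-day year convention).
DAYS_PER_STEP <- 365 / 36

#' Second-order harmonic design matrix
#'
#' Builds the seasonal regressors sin/cos(2*pi*h*t/period) for h = 1, 2 at
#' global step indices `t`, so that segments share a common phase origin.
#'
#' @param t Integer step indices.
#' @param period Steps per year (36).
#' @param order Harmonic order (2).
#' @return Matrix with `2 * order` columns (sin1, cos1, sin2, cos2, ...).
#' @export
harmonic_design <- function(t, period = 36L, order = 2L) {
  stopifnot(order >= 1L)
  cols <- lapply(seq_len(order), function(h) {
    w <- 2 * pi * h * t / period
    cbind(sin(w), cos(w))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- as.vector(rbind(paste0("sin", seq_len(order)),
                                 paste0("cos", seq_len(order))))
  X
}

# Wrap a difference in days to (-182.5, 182.5].
wrap_days <- function(x) {
  w <- (x + 182.5) %% 365 - 182.5
  ifelse(w <= -182.5, w + 365, w)
}
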