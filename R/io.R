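#' @title Text-based input/output
#' @description Plain-text serialization: per-pixel series as 2-column CSV,
#'   scenes as a directory of CSV tables plus a YAML configuration, and
#'   analysis outputs as CSV/JSON.
#' @name io
NULL

#' Write / read a single series as CSV
#'
#' Two columns: `time` (decimal year, mid-composite convention) and
#' `value`; missing composites have empty values.
#'
#' @param x A [ts10d].
#' @param path CSV path.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "ts10d"))
  utils::write.csv(data.frame(time = ts10d_time(x), value = x$values),
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @return `read_series_csv` returns a [ts10d].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "value") %in% names(df)))
  ts10d(df$value, start_year = floor(df$time[1]))
}

#' Read a scene configuration from YAML
#'
#' Top-level keys mirror the arguments of [scene_config()]; `event_params`
#' is a mapping of `[mean, sd]` pairs.
#'
#' @param path YAML file.
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$event_params))
    y$event_params <- lapply(y$event_params, as.numeric)
  if (!is.null(y$driver_mix)) y$driver_mix <- unlist(y$driver_mix)
  if (!is.null(y$attribution_shares))
    y$attribution_shares <- unlist(y$attribution_shares)
  do.call(scene_config, y)
}

#' Write / read a scene as plain-text files
#'
#' The three stacks are stored as `<var>.csv` matrices (rows = time steps,
#' columns = pixels in column-major order), the static rasters as
#' `static.csv`, the truth table as `truth.csv` and the configuration as
#' `config.yaml`. Intended for small demonstration scenes.
#'
#' @param scene An [make_scene()] scene.
#' @param dir Output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "lst_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cf <- scene$config
  for (v in c("lst", "albedo", "et")) {
    m <- matrix(scene[[v]], dim(scene[[v]])[1])
    utils::write.csv(m, file.path(dir, paste0(v, ".csv")),
                     row.names = FALSE, na = "")
  }
  st <- scene_pixels(scene)
  st$loss_year <- as.vector(scene$loss_year)
  st$loss_pct <- as.vector(scene$loss_pct)
  st$driver <- as.vector(scene$driver)
  st$boreal <- as.vector(scene$boreal)
  st$region <- as.vector(scene$region)
  utils::write.csv(st, file.path(dir, "static.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, na = "")
  cfy <- cf
  class(cfy) <- NULL
  yaml::write_yaml(cfy, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @return `read_scene` returns the reconstructed `lst_scene` (truth
#'   attributes such as the shared anomaly series are not round-tripped).
#' @export
read_scene <- function(dir) {
  cf <- read_scene_config(file.path(dir, "config.yaml"))
  nr <- cf$nrow; nc <- cf$ncol
  n <- (cf$end_year - cf$start_year + 1L) * 36L
  stacks <- lapply(c("lst", "albedo", "et"), function(v) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(v, ".csv"))))
    array(as.numeric(m), dim = c(n, nr, nc))
  })
  names(stacks) <- c("lst", "albedo", "et")
  st <- utils::read.csv(file.path(dir, "static.csv"),
                        stringsAsFactors = FALSE)
  as_mat <- function(v) matrix(as.numeric(st[[v]]), nr, nc)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  structure(
    list(config = cf, lst = stacks$lst, albedo = stacks$albedo,
         et = stacks$et,
         elevation = as_mat("elevation"),
         landcover = matrix(st$landcover, nr, nc),
         cover2000 = as_mat("cover_pct"),
         loss_year = matrix(as.integer(st$loss_year), nr, nc),
         loss_pct = as_mat("loss_pct"),
         driver = matrix(st$driver, nr, nc),
         lat = as_mat("lat"), boreal = matrix(st$boreal, nr, nc),
         region = matrix(st$region, nr, nc), truth = truth,
         base_seasonal_coef = NULL, anomaly_year = NULL),
    class = "lst_scene")
}

# Write the standard analysis artifacts of a run.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(run$attribution))
    utils::write.csv(run$attribution, file.path(dir, "attribution.csv"),
                     row.names = FALSE, na = "")
  utils::write.csv(run$zonal, file.path(dir, "zonal_summary.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(run$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(run$log, file.path(dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
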