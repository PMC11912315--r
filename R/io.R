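#' Read and write driver series as CSV
#'
#' Columns: `date` (decimal year), `value`, `kind`, `units`.  Values
#' round-trip at full double precision.
#'
#' @param fs a [factor_series()].
#' @param path file path.
#' @return `write_factor_series` returns `path` invisibly;
#'   `read_factor_series` returns a [factor_series()].
#' @export
write_factor_series <- function(fs, path) {
  stopifnot(inherits(fs, "factor_series"))
  df <- data.frame(date = format_full(fs$timestamps),
                   value = format_full(fs$values),
                   kind = fs$kind, units = fs$units)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_factor_series
#' @export
read_factor_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  factor_series(as.numeric(df$date), as.numeric(df$value),
                kind = df$kind[1], units = as.character(df$units[1]))
}

## full-precision decimal text (round-trips doubles exactly)
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write anomaly series as CSV
#'
#' Columns: `year`, `anomaly_fraction`, plus one `smoothed_<w>yr` column
#' per requested smoothing window.
#'
#' @param series an `anomaly_series`.
#' @param path file path.
#' @param windows smoothing windows to include; default `c(4, 7)`.
#' @return `write_anomaly_csv` returns `path` invisibly;
#'   `read_anomaly_csv` returns an `anomaly_series` (smoothed columns are
#'   kept in attribute `"smoothed"`).
#' @export
write_anomaly_csv <- function(series, path, windows = c(4, 7)) {
  stopifnot(inherits(series, "anomaly_series"))
  df <- data.frame(year = series$years,
                   anomaly_fraction = format_full(series$values))
  for (w in windows[windows <= length(series$values)])
    df[[sprintf("smoothed_%dyr", w)]] <-
      format_full(moving_average(series$values, w))
  attr(df, "reference_year") <- series$reference_year
  utils::write.csv(cbind(df, reference_year = series$reference_year),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anomaly_csv
#' @export
read_anomaly_csv <- function(path) {
  df <- utils::read.csv(path)
  ref <- if ("reference_year" %in% names(df)) df$reference_year[1]
         else NA_real_
  out <- anomaly_series_new(df$year, as.numeric(df$anomaly_fraction), ref)
  sm <- grep("^smoothed_", names(df), value = TRUE)
  if (length(sm))
    attr(out, "smoothed") <- lapply(stats::setNames(df[sm], sm), as.numeric)
  out
}

#' Read and write wildfire event tables as CSV
#'
#' @param events data frame with at least `year` and `area_ha`.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path)
}

#' Read and write scenario trajectories as CSV
#'
#' Columns: `year`, `delta_T_C`, `co2_ratio`; the label travels in a
#' `label` column.
#'
#' @param traj a [scenario_trajectory()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "scenario_trajectory"))
  utils::write.csv(data.frame(year = traj$years,
                              delta_T_C = format_full(traj$delta_t),
                              co2_ratio = format_full(traj$co2_ratio),
                              label = traj$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scenario_trajectory(df$year, as.numeric(df$delta_T_C),
                      as.numeric(df$co2_ratio),
                      label = if ("label" %in% names(df)) df$label[1] else "")
}

## integer codes for the fixed PFT vocabulary in .asc rasters
pft_codes <- function() {
  stats::setNames(seq_along(pft_classes()), pft_classes())
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text single-band raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header, then rows north to south).  Anomaly
#' fields are written as numeric values with nodata for masked pixels;
#' PFT grids are written as the integer codes of [pft_classes()] in
#' vocabulary order (forest = 1, ..., other = 5).
#'
#' @param x a [grid_field()] or [pft_grid()].
#' @param path file path (`.asc`).
#' @return writers return `path` invisibly; readers return the
#'   reconstructed object.
#' @export
write_grid_asc <- function(x, path) {
  if (inherits(x, "pft_grid")) {
    m <- matrix(pft_codes()[x$classes], nrow(x$classes), ncol(x$classes))
    nodata <- -9999
    px <- x$pixel_size; orig <- x$origin
  } else if (inherits(x, "grid_field")) {
    m <- x$values
    nodata <- -9999
    px <- x$pixel_size; orig <- x$origin
  } else stop("write_grid_asc handles pft_grid and grid_field objects")
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %s", format_full(orig[1])),
           sprintf("yllcorner %s", format_full(orig[2])),
           sprintf("cellsize %s", format_full(px)),
           sprintf("NODATA_value %d", nodata))
  rows <- apply(m, 1, function(r) paste(format_full(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_grid_asc
#' @param as either `"field"` (numeric [grid_field()]) or `"pft"`
#'   (decode integer codes back to a [pft_grid()]).
#' @export
read_grid_asc <- function(path, as = c("field", "pft")) {
  as <- match.arg(as)
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  hv <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                        vapply(hdr, `[`, character(1), 1))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == hv[["nodata_value"]]] <- NA_real_
  origin <- c(hv[["xllcorner"]], hv[["yllcorner"]])
  if (as == "pft") {
    codes <- pft_codes()
    cls <- matrix(names(codes)[m], nrow(m), ncol(m))
    pft_grid(cls, pixel_size = hv[["cellsize"]], origin = origin)
  } else {
    grid_field(m, pixel_size = hv[["cellsize"]], origin = origin)
  }
}

#' Write a JSON report
#'
#' @param x a named list.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Bundled worked example of the Germany 1979-2024 analysis
#'
#' Loads the packaged YAML fixture holding the per-driver contributions,
#' the Lueneburg Heath wildfire event, the seasonal-analysis quantities
#' and the endpoint driver changes of the reference analysis, so worked
#' examples and acceptance checks need no generation step.
#'
#' @return named list mirroring the fixture structure.
#' @export
worked_example <- function() {
  path <- system.file("extdata", "germany_1979_2024.yaml",
                      package = "bvocanom", mustWork = TRUE)
  yaml::read_yaml(path)
}
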