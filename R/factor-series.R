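#' Driver time series
#'
#' A `factor_series` holds one driver's time-stamped values: decimal-year
#' timestamps, values in the driver's native units, the driver kind and a
#' free-text units label.  It is the common currency of the attribution
#' pipeline.
#'
#' @param timestamps numeric vector of decimal years, strictly increasing.
#' @param values numeric vector, same length as `timestamps`; must be
#'   finite.  NDVI values must lie in `[-1, 1]`; soil moisture must be
#'   non-negative.
#' @param kind one of `"NDVI"`, `"temperature"`, `"CO2"`, `"soil_moisture"`.
#' @param units units label, e.g. `"degC"` or `"kg/m2"`.
#' @return an object of class `factor_series`.
#' @examples
#' fs <- factor_series(2000:2004, c(8.1, 8.3, 8.0, 8.6, 8.9),
#'                     kind = "temperature", units = "degC")
#' annual_means(fs)
#' @export
factor_series <- function(timestamps, values, kind, units = "") {
  kind <- match.arg(kind, driver_kinds())
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("timestamps and values must have the same length")
  if (length(timestamps) == 0L)
    stop("factor_series must contain at least one observation")
  if (any(!is.finite(timestamps)) || any(!is.finite(values)))
    stop("factor_series must not contain non-finite values")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (kind == "NDVI" && (any(values < -1) || any(values > 1)))
    stop("NDVI values must lie in [-1, 1]")
  if (kind == "soil_moisture" && any(values < 0))
    stop("soil moisture values must be non-negative")
  structure(list(timestamps = timestamps, values = values,
                 kind = kind, units = units),
            class = "factor_series")
}

driver_kinds <- function() c("NDVI", "temperature", "CO2", "soil_moisture")

#' @export
print.factor_series <- function(x, ...) {
  cat(sprintf("<factor_series> kind=%s units='%s' n=%d span=%.2f-%.2f\n",
              x$kind, x$units, length(x$values),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Calendar-year means of a driver series
#'
#' Collapses a (possibly sub-annual) `factor_series` to one mean value per
#' calendar year.  Used to annualise drivers before computing year-on-year
#' contributions.
#'
#' @param fs a [factor_series()].
#' @return named numeric vector of per-year means; names are the years.
#' @export
annual_means <- function(fs) {
  stopifnot(inherits(fs, "factor_series"))
  yr <- floor(fs$timestamps)
  out <- tapply(fs$values, yr, mean)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

## samples per year, inferred from the timestamp grid
series_cadence <- function(fs) {
  yr <- floor(fs$timestamps)
  as.integer(round(max(table(yr))))
}
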