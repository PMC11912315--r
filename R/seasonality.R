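#' Seasonal amplitude of a sub-annual driver series
#'
#' Amplitude is defined on the raw cadence, without a harmonic fit: for
#' every complete calendar year, amplitude = (max - min) / 2.  The summary
#' also reports the change over the record, as an OLS trend times the span
#' in years, both for the half-range amplitude and for the full intra-year
#' range (max - min) -- it is the *range* change that feeds the
#' temperature amplification (e.g. minima warming by 1.65 degC while
#' maxima warm by 2.15 degC is a 0.5 degC range increase).
#'
#' @param series a [factor_series()] with at least 4 samples per year and
#'   at least 2 complete years.
#' @return an object of class `seasonal_summary`: list with `years`,
#'   `amplitude` (per-year half-range), `amplitude_change`,
#'   `range_change`, and `kind`.
#' @export
seasonal_amplitude <- function(series) {
  stopifnot(inherits(series, "factor_series"))
  yr <- floor(series$timestamps)
  counts <- table(yr)
  cadence <- max(counts)
  if (cadence < 4)
    stop("seasonal_amplitude needs at least 4 samples per year")
  complete <- as.numeric(names(counts)[counts == cadence])
  if (length(complete) < 2)
    stop("seasonal_amplitude needs at least 2 complete years")
  amp <- vapply(complete, function(y) {
    v <- series$values[yr == y]
    (max(v) - min(v)) / 2
  }, numeric(1))
  span <- max(complete) - min(complete)
  slope <- stats::coef(stats::lm(amp ~ complete))[[2]]
  structure(list(years = complete, amplitude = amp,
                 amplitude_change = slope * span,
                 range_change = 2 * slope * span,
                 kind = series$kind),
            class = "seasonal_summary")
}

#' @export
print.seasonal_summary <- function(x, ...) {
  cat(sprintf("<seasonal_summary> kind=%s years=%d range_change=%.4g\n",
              x$kind, length(x$years), x$range_change))
  invisible(x)
}

#' Seasonal amplification of BVOC emissions
#'
#' Translates an increase in the seasonal temperature range and a seasonal
#' biomass change into the amplification of the emission seasonal cycle.
#' The temperature part is `exp(beta * dA) - 1`; the total is the plain
#' sum of the temperature and biomass parts (additive convention: 5.13% +
#' 6.13% = 11.26%).
#'
#' @param temp_amplitude_change increase of the seasonal temperature range,
#'   degC.
#' @param beta temperature coefficient, per degC.
#' @param biomass_seasonal_change seasonal biomass change, fraction.
#' @return list with `temperature`, `biomass` and `total` (fractions).
#' @examples
#' seasonal_amplification(0.5, 0.1, 0.0613)  # ~ (0.0513, 0.0613, 0.1126)
#' @export
seasonal_amplification <- function(temp_amplitude_change, beta = 0.1,
                                   biomass_seasonal_change = 0) {
  if (beta < 0) stop("beta must be non-negative")
  tpart <- exp(beta * temp_amplitude_change) - 1
  list(temperature = tpart, biomass = biomass_seasonal_change,
       total = tpart + biomass_seasonal_change)
}

#' Convert a seasonal NDVI change to a seasonal biomass change
#'
#' The seasonal biomass increase is inferred proportionally from the
#' seasonal NDVI increase.  The proportionality constant is a
#' configuration input; its default (6.13 / 9.5) reproduces the worked
#' chain in which a 9.5% seasonal NDVI increase maps to a 6.13% seasonal
#' biomass increase.
#'
#' @param ndvi_seasonal_change fractional seasonal NDVI change.
#' @param coefficient NDVI-to-biomass seasonal proportionality.
#' @return fractional seasonal biomass change.
#' @export
ndvi_seasonal_to_biomass <- function(ndvi_seasonal_change,
                                     coefficient = 6.13 / 9.5) {
  if (coefficient < 0) stop("coefficient must be non-negative")
  ndvi_seasonal_change * coefficient
}
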