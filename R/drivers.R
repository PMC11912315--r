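#' Response parameters of the emission model
#'
#' Bundles the scalar coefficients of the per-driver responses.
#'
#' @param beta_t temperature coefficient, per degC.  Default 0.1, the
#'   conventional constant of the exponential temperature-correction
#'   factor (MEGAN-style species-specific values range 0.1-0.2).
#' @param beta_co2 CO2 sensitivity of isoprene, dimensionless.  Default
#'   0.33, a conifer-weighted average (conifers 0.25-0.30, broadleaves
#'   higher; MEGAN's global average is 0.5).
#' @param isoprene_share fraction of total BVOC emission that is isoprene;
#'   default 0.5.  Only isoprene responds to CO2.
#' @param dry_scaling green-to-dry biomass conversion for wildfire
#'   calculations; default 0.5.
#' @param background_rate typical temperate-forest emission rate,
#'   kg/ha/day; default 0.26.  Used as the denominator of wildfire rate
#'   ratios.
#' @return an object of class `response_params`.
#' @export
response_params <- function(beta_t = 0.1, beta_co2 = 0.33,
                            isoprene_share = 0.5, dry_scaling = 0.5,
                            background_rate = 0.26) {
  vals <- c(beta_t = beta_t, beta_co2 = beta_co2,
            isoprene_share = isoprene_share, dry_scaling = dry_scaling,
            background_rate = background_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("response parameters must be finite and non-negative; offending: ",
         paste(names(vals)[!is.finite(vals) | vals < 0], collapse = ", "))
  if (isoprene_share > 1) stop("isoprene_share must lie in [0, 1]")
  if (dry_scaling > 1) stop("dry_scaling must lie in [0, 1]")
  structure(as.list(vals), class = "response_params")
}

#' Per-class NDVI-to-biomass regression model
#'
#' Linear per-class models `biomass = intercept + slope * NDVI` (t/ha),
#' each valid on a stated NDVI range.  Coefficients are configuration
#' inputs fitted elsewhere (to field samples), not fitted here.
#'
#' @param table data frame with columns `class`, `intercept` (t/ha),
#'   `slope` (t/ha per NDVI unit), `ndvi_min`, `ndvi_max`.  Slopes of
#'   vegetated classes must be positive.
#' @return an object of class `biomass_model`.
#' @seealso [default_biomass_model()]
#' @export
biomass_model <- function(table) {
  req <- c("class", "intercept", "slope", "ndvi_min", "ndvi_max")
  if (!all(req %in% names(table)))
    stop("biomass_model table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(table$class)) stop("duplicate class in biomass_model")
  if (any(table$slope <= 0))
    stop("slope must be positive for vegetated classes")
  if (any(table$ndvi_max <= table$ndvi_min))
    stop("ndvi_max must exceed ndvi_min")
  structure(list(table = table), class = "biomass_model")
}

#' Default NDVI-to-biomass models
#'
#' Forest is tuned so that peak forest NDVI (0.85) maps to 293 t/ha, the
#' standing green biomass density of temperate forest used in the wildfire
#' calculus.  Agriculture and grassland slopes are illustrative crop/grass
#' standing-biomass magnitudes; all three are meant to be replaced by
#' study-specific regression fits via the configuration file.
#'
#' @return a [biomass_model()].
#' @export
default_biomass_model <- function() {
  biomass_model(data.frame(
    class     = c("forest", "agriculture", "grassland"),
    intercept = c(0, 0, 0),
    slope     = c(293 / 0.85, 20, 12),
    ndvi_min  = 0,
    ndvi_max  = 1
  ))
}

#' Convert NDVI to biomass density
#'
#' Evaluates the class's linear regression `intercept + slope * NDVI`.
#' Negative predictions are clamped to 0 with a warning (physicality over
#' strict linearity).
#'
#' @param ndvi NDVI value(s) inside the model's valid range.
#' @param class a single PFT class known to the model.
#' @param model a [biomass_model()].
#' @return biomass density, t/ha (vectorised over `ndvi`).
#' @export
ndvi_to_biomass <- function(ndvi, class, model = default_biomass_model()) {
  stopifnot(inherits(model, "biomass_model"))
  row <- model$table[model$table$class == class, ]
  if (nrow(row) != 1L)
    stop("unknown class for biomass model: ", class)
  if (any(ndvi < row$ndvi_min | ndvi > row$ndvi_max))
    stop(sprintf("NDVI outside valid range [%g, %g] for class '%s'",
                 row$ndvi_min, row$ndvi_max, class))
  b <- row$intercept + row$slope * ndvi
  if (any(b < 0)) {
    warning("negative predicted biomass clamped to 0")
    b <- pmax(b, 0)
  }
  b
}

#' Area-weighted biomass contribution
#'
#' Combines per-class relative biomass changes into the total biomass
#' contribution: `part_c = weight_c * change_c`, total = sum of parts.
#'
#' @param per_class_relative_change named numeric vector, fractional
#'   biomass change per class.
#' @param per_class_weight named numeric vector of non-negative area
#'   weights; must cover exactly the same classes.
#' @return list with `total` (fraction) and `parts` (named fractions).
#' @examples
#' # forest/agriculture/grassland parts of 8.34/14.05/1.65% -> 24% total
#' w <- c(forest = 1/3, agriculture = 1/2, grassland = 1/6)
#' ch <- c(forest = 0.0834, agriculture = 0.1405, grassland = 0.0165) / w
#' biomass_contribution(ch, w)$total
#' @export
biomass_contribution <- function(per_class_relative_change, per_class_weight) {
  ch <- per_class_relative_change
  w <- per_class_weight
  if (!setequal(names(ch), names(w)))
    stop("class sets of changes and weights do not match")
  if (any(w < 0)) stop("weights must be non-negative")
  w <- w[names(ch)]
  parts <- w * ch
  list(total = sum(parts), parts = parts)
}

#' Exponential temperature response
#'
#' Fractional emission change `exp(beta * delta_t) - 1` for a temperature
#' offset `delta_t`.  With the conventional `beta = 0.1` a 10 degC warming
#' multiplies emissions by `e` (~2.72); the literal Q10 = 2 doubling
#' corresponds to `beta = log(2)/10`.
#'
#' @param delta_t temperature change, degC.
#' @param beta temperature coefficient, per degC (>= 0).
#' @return fractional emission change (vectorised).
#' @examples
#' temperature_activity(1.88)        # ~0.207: +20.7%
#' temperature_activity(10, log(2) / 10)  # exactly 1: Q10 doubling
#' @export
temperature_activity <- function(delta_t, beta = 0.1) {
  if (any(!is.finite(delta_t))) stop("delta_t must be finite")
  if (beta < 0) stop("beta must be non-negative")
  exp(beta * delta_t) - 1
}

#' CO2 inhibition of isoprene emission
#'
#' Fractional isoprene change as a power law of the CO2 concentration
#' ratio: `(C/C0)^(-beta_co2) - 1`.  Decreasing in the ratio: lower CO2
#' enhances isoprene emission.
#'
#' @param concentration_ratio `C/C0`, current over reference CO2
#'   concentration (> 0).
#' @param beta_co2 sensitivity factor (>= 0).
#' @return fractional isoprene emission change (vectorised).
#' @examples
#' co2_activity(0.62, 0.33)   # ~0.17: +17% isoprene for a 38% CO2 decrease
#' @export
co2_activity <- function(concentration_ratio, beta_co2 = 0.33) {
  if (any(!is.finite(concentration_ratio)) || any(concentration_ratio <= 0))
    stop("concentration_ratio must be positive")
  if (beta_co2 < 0) stop("beta_co2 must be non-negative")
  concentration_ratio^(-beta_co2) - 1
}

#' Scale an isoprene change to total BVOC
#'
#' Isoprene constitutes roughly half of total BVOC emission and is the
#' only component with a recognised CO2 response, so a fractional isoprene
#' change maps to `change * share` of total BVOC.
#'
#' @param isoprene_change fractional isoprene change.
#' @param isoprene_share isoprene's share of total BVOC, in `[0, 1]`.
#' @return fractional total-BVOC change.
#' @export
isoprene_to_total <- function(isoprene_change, isoprene_share = 0.5) {
  if (isoprene_share < 0 || isoprene_share > 1)
    stop("isoprene_share must lie in [0, 1]")
  isoprene_change * isoprene_share
}

#' Soil-moisture contribution
#'
#' Linear soil-flux response: the fractional emission change equals the
#' relative soil-moisture anomaly `(SM - SM0) / SM0`.
#'
#' @param sm current soil moisture (driver units).
#' @param sm0 reference soil moisture (> 0, same units).
#' @return fractional emission change (vectorised over `sm`).
#' @export
soil_moisture_contribution <- function(sm, sm0) {
  if (!is.finite(sm0) || sm0 <= 0) stop("sm0 must be positive")
  (sm - sm0) / sm0
}

#' Wildfire burnt-area event
#'
#' @param area burnt area, ha (>= 0).
#' @param forest_fraction fraction of the burnt area that is forest.
#' @param green_biomass_density standing green biomass, t/ha.
#' @param emission_factors data frame with columns `value` (g emitted per
#'   kg dry burnt biomass) and `weight`; weights must sum to 1.
#' @param duration burn duration in days, or `NA` if unknown.
#' @return an object of class `wildfire_event`.
#' @export
wildfire_event <- function(area, forest_fraction = 1,
                           green_biomass_density = 293,
                           emission_factors = data.frame(value = c(0.5, 0.2),
                                                         weight = c(0.5, 0.5)),
                           duration = NA_real_) {
  if (area < 0) stop("area must be non-negative")
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("forest_fraction must lie in [0, 1]")
  if (nrow(emission_factors) == 0) stop("emission_factors must be non-empty")
  if (abs(sum(emission_factors$weight) - 1) > 1e-9)
    stop("emission factor weights must sum to 1")
  structure(list(area = area, forest_fraction = forest_fraction,
                 green_biomass_density = green_biomass_density,
                 emission_factors = emission_factors, duration = duration),
            class = "wildfire_event")
}

#' Dry burnt biomass of a wildfire event
#'
#' `area * forest_fraction * green_biomass_density * dry_scaling`.
#'
#' @param event a [wildfire_event()].
#' @param dry_scaling green-to-dry conversion fraction.
#' @return dry biomass, t.
#' @examples
#' ev <- wildfire_event(4840, 0.9, 293)
#' wildfire_dry_biomass(ev)   # 638154 t, ~0.638 million t
#' @export
wildfire_dry_biomass <- function(event, dry_scaling = 0.5) {
  stopifnot(inherits(event, "wildfire_event"))
  if (dry_scaling < 0 || dry_scaling > 1)
    stop("dry_scaling must lie in [0, 1]")
  event$area * event$forest_fraction * event$green_biomass_density *
    dry_scaling
}

#' BVOC emission from dry burnt biomass
#'
#' `dry_mass * sum(weight * ef) * 1e-3` (g/kg converted to t/t).
#'
#' @param dry_mass dry burnt biomass, t.
#' @param emission_factors data frame with columns `value` (g/kg) and
#'   `weight` summing to 1.
#' @return emitted mass, t.
#' @export
wildfire_emission <- function(dry_mass,
                              emission_factors = data.frame(value = c(0.5, 0.2),
                                                            weight = c(0.5, 0.5))) {
  if (nrow(emission_factors) == 0) stop("emission_factors must be non-empty")
  if (abs(sum(emission_factors$weight) - 1) > 1e-9)
    stop("emission factor weights must sum to 1")
  dry_mass * sum(emission_factors$weight * emission_factors$value) * 1e-3
}

#' Wildfire emission rate and ratio to background
#'
#' Converts an emitted mass over an area and duration to kg/ha/day, and
#' compares it with the typical temperate-forest background rate.
#'
#' @param emitted emitted mass, t.
#' @param area burnt area, ha (> 0).
#' @param duration burn duration, days (> 0).
#' @param background_rate background emission rate, kg/ha/day.
#' @return list with `rate` (kg/ha/day) and `ratio` (rate / background).
#' @export
wildfire_rate <- function(emitted, area, duration, background_rate = 0.26) {
  if (area <= 0 || duration <= 0)
    stop("area and duration must be positive")
  rate <- emitted * 1e3 / (area * duration)
  list(rate = rate, ratio = rate / background_rate)
}
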