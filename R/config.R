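#' Default run configuration
#'
#' Returns the full default configuration list used by [run_pipeline()].
#' All coefficients are documented in [response_params()],
#' [default_biomass_model()] and [error_budget()].
#'
#' @return named list with a `schema_version` field.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    reference_year = 1978,
    seed = 1L,
    coefficients = list(
      beta_t = 0.1,
      beta_co2 = 0.33,
      isoprene_share = 0.5,
      dry_scaling = 0.5,
      background_rate = 0.26,
      ndvi_seasonal_to_biomass = 6.13 / 9.5,
      temp_biomass_coupling = 0.24 / 1.88
    ),
    class_weights = list(forest = 1 / 3, agriculture = 1 / 2,
                         grassland = 1 / 6),
    biomass_model = list(
      forest = list(intercept = 0, slope = 293 / 0.85,
                    ndvi_min = 0, ndvi_max = 1),
      agriculture = list(intercept = 0, slope = 20,
                         ndvi_min = 0, ndvi_max = 1),
      grassland = list(intercept = 0, slope = 12,
                       ndvi_min = 0, ndvi_max = 1)
    ),
    error_budget = list(biomass = 0.03, temperature = 0.03,
                        soil_moisture = 0.10, co2 = 0.20,
                        method = "linear_sum"),
    smoothing_windows = c(4L, 7L),
    spatial = list(radius_km = 15, pixel_size = 500, kernel = "disc",
                   urban_model_class = "agriculture"),
    inputs = list()
  )
}

## numeric-range checks; each failure names the offending field
config_checks <- list(
  beta_t = function(v) v >= 0,
  beta_co2 = function(v) v >= 0,
  isoprene_share = function(v) v >= 0 && v <= 1,
  dry_scaling = function(v) v >= 0 && v <= 1,
  background_rate = function(v) v > 0,
  ndvi_seasonal_to_biomass = function(v) v >= 0,
  temp_biomass_coupling = function(v) is.finite(v)
)

#' Validate a run configuration
#'
#' Checks schema version, required blocks and the physical ranges of all
#' coefficients.  Errors carry the offending field name.
#'
#' @param config configuration list (see [default_config()]).
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  if (is.null(config$schema_version) || config$schema_version != 1L)
    stop("config field 'schema_version' must be 1")
  for (block in c("reference_year", "coefficients", "class_weights",
                  "error_budget"))
    if (is.null(config[[block]]))
      stop("config field '", block, "' is missing")
  for (nm in names(config_checks)) {
    v <- config$coefficients[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || !config_checks[[nm]](v))
      stop("config field '", nm, "' is out of its physical range")
  }
  w <- unlist(config$class_weights)
  if (any(w < 0)) stop("config field 'class_weights' must be non-negative")
  eb <- config$error_budget
  if (any(unlist(eb[setdiff(names(eb), "method")]) < 0))
    stop("config field 'error_budget' margins must be non-negative")
  if (!is.null(config$spatial$radius_km) && config$spatial$radius_km < 0)
    stop("config field 'radius_km' must be non-negative")
  invisible(config)
}

#' Read a YAML run configuration
#'
#' Missing blocks are filled from [default_config()]; the result is
#' validated with [validate_config()].
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  validate_config(config)
  config
}

## materialise config blocks as package objects
config_params <- function(config) {
  co <- config$coefficients
  response_params(beta_t = co$beta_t, beta_co2 = co$beta_co2,
                  isoprene_share = co$isoprene_share,
                  dry_scaling = co$dry_scaling,
                  background_rate = co$background_rate)
}

config_biomass_model <- function(config) {
  rows <- lapply(names(config$biomass_model), function(cl) {
    b <- config$biomass_model[[cl]]
    data.frame(class = cl, intercept = b$intercept, slope = b$slope,
               ndvi_min = b$ndvi_min, ndvi_max = b$ndvi_max)
  })
  biomass_model(do.call(rbind, rows))
}

config_error_budget <- function(config) {
  eb <- config$error_budget
  error_budget(biomass = eb$biomass, temperature = eb$temperature,
               soil_moisture = eb$soil_moisture, co2 = eb$co2,
               method = eb$method)
}
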