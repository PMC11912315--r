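# Shared fixtures, all built in code.

derive_seed <- bvocanom:::derive_seed

# Contribution set of the Germany 1979-2024 reference analysis.
reference_contributions <- function() {
  contribution_set(biomass = 0.24, temperature = 0.207, co2 = 0.085,
                   soil_moisture = -0.0528)
}

ref_class_weights <- c(forest = 1 / 3, agriculture = 1 / 2, grassland = 1 / 6)
ref_biomass_parts <- c(forest = 0.0834, agriculture = 0.1405,
                       grassland = 0.0165)

# Synthetic driver set whose 2024 endpoint reproduces the reference
# analysis: dT = +1.88 degC, CO2 ratio 0.62, soil moisture -5.28%, and
# per-class biomass parts 8.34/14.05/1.65% under the default weights.
# With intercept-0 biomass models the relative biomass change equals the
# relative NDVI change, so NDVI trends encode the prescribed parts.
endpoint_drivers <- function(cadence = 1, noise = FALSE, seed = 1) {
  span <- 2024 - 1978
  mk <- function(baseline, endpoint_change_abs, sd, amp = 0, purpose) {
    generate_driver_series(
      gen_spec(1978, 2024, cadence = cadence, baseline = baseline,
               trend = endpoint_change_abs / span,
               seasonal_amplitude = amp, noise_sd = if (noise) sd else 0,
               seed = derive_seed(seed, purpose)),
      kind = purpose_kind(purpose))
  }
  ndvi_base <- c(forest = 0.6, agriculture = 0.5, grassland = 0.5)
  ndvi_change <- ref_biomass_parts / ref_class_weights  # relative change
  ndvi <- lapply(names(ndvi_base), function(cl)
    mk(ndvi_base[[cl]], ndvi_base[[cl]] * ndvi_change[[cl]], sd = 0.02,
       amp = 0.15 * (cadence > 1), purpose = paste0("NDVI_", cl)))
  names(ndvi) <- names(ndvi_base)
  list(
    ndvi = ndvi,
    temperature = mk(8, 1.88, sd = 0.3, amp = 8 * (cadence > 1),
                     purpose = "temperature"),
    co2 = mk(1, -0.38, sd = 0.002, purpose = "CO2"),
    soil_moisture = mk(25, 25 * -0.0528, sd = 0.5, purpose = "soil_moisture")
  )
}

purpose_kind <- function(purpose) {
  if (startsWith(purpose, "NDVI")) "NDVI" else purpose
}

# Truth of the endpoint contributions implied by endpoint_drivers().
endpoint_truth <- function() {
  list(biomass = sum(ref_biomass_parts),
       temperature = temperature_activity(1.88, 0.1),
       co2 = isoprene_to_total(co2_activity(0.62, 0.33), 0.5),
       soil_moisture = -0.0528)
}

# independent reimplementation of the stated generator model curve
spec_curve_for_test <- function(spec) {
  n <- (spec$end_year - spec$start_year + 1) * spec$cadence
  t <- spec$start_year + (seq_len(n) - 1) / spec$cadence
  dt <- t - spec$start_year
  amp <- spec$seasonal_amplitude + spec$seasonal_amplitude_trend * dt
  spec$baseline + spec$trend * dt + amp * cos(2 * pi * ((t - floor(t)) - 0.5))
}

# seeded Gaussian noise that leaves the caller's RNG state untouched
with_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n, 0, sd)
}

# small single-class grid + NDVI stack + uniform environment, zero noise
uniform_spatial_fixture <- function(class = "forest", n = 6,
                                    end_year = 1990) {
  pft <- pft_grid(matrix(class, n, n), pixel_size = 500)
  spec <- gen_spec(1978, end_year, baseline = 0.6,
                   trend = 0.002, seed = 11)
  stack <- generate_gridded_ndvi(pft, stats::setNames(list(spec), class))
  env <- list(
    temperature = generate_driver_series(
      gen_spec(1978, end_year, baseline = 8, trend = 0.04, seed = 1),
      "temperature"),
    co2 = generate_driver_series(
      gen_spec(1978, end_year, baseline = 1, trend = -0.004, seed = 2),
      "CO2"),
    soil_moisture = generate_driver_series(
      gen_spec(1978, end_year, baseline = 25, trend = -0.02, seed = 3),
      "soil_moisture"))
  list(pft = pft, stack = stack, env = env, spec = spec)
}
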