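# Reference worked example: Germany, 1979-2024 satellite era.
# Per-driver endpoint changes and contributions of the national-scale
# BVOC anomaly analysis, bundled so reports and tests need no
# generation or download step.
label: germany_1979_2024
reference_year: 1978
endpoint_year: 2024
drivers:
  delta_t_c: 1.88            # observed warming over the record, degC
  co2_ratio: 0.62            # CO2 concentration ratio vs reference (-38%)
  sm_relative_anomaly: -0.0528
contributions:
  biomass: 0.24
  biomass_parts:
    forest: 0.0834
    agriculture: 0.1405
    grassland: 0.0165
  temperature: 0.207
  co2: 0.085
  soil_moisture: -0.0528
wildfire_event:              # Lueneburg Heath 1996, the largest recent fire
  area_ha: 4840
  forest_fraction: 0.9
  green_biomass_density_t_ha: 293   # temperate-forest standing biomass
  dry_scaling: 0.5
  emission_factors:          # Scots pine / English oak, g per kg dry biomass
    - {value: 0.5, weight: 0.5}
    - {value: 0.2, weight: 0.5}
  duration_days: 19.2        # back-solved so the rate matches ~2.4 kg/ha/day;
                             # an assumption, not an observation
seasonal:
  temperature_range_change_c: 0.5   # minima +1.65, maxima +2.15 degC
  min_trend_c: 1.65
  max_trend_c: 2.15
  ndvi_seasonal_change: 0.095
  biomass_seasonal_change: 0.0613
trend_regimes:               # piecewise slopes of the smoothed anomaly
  - {start: 1987, end: 2005, slope_pct_per_yr: 2.4}
  - {start: 2006, end: 2020, slope_pct_per_yr: 0.6}
  - {start: 2021, end: 2024, slope_pct_per_yr: -1.2}
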