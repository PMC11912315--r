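# bvocanom

Attribution of long-term anomalies in biogenic volatile organic compound
(BVOC) emissions to their principal drivers.

## The problem

BVOCs (isoprene, monoterpenes, sesquiterpenes) are emitted by vegetation
and soil biota; they feed ground-level ozone and secondary organic
aerosol and interact with climate.  Direct long-term measurements do not
exist, but the *fractional change* of emissions relative to a reference
year can be reconstructed from remotely sensed proxies.  Writing emission
as emitter × emission factor and cancelling the constant species-specific
part, the anomaly decomposes into per-driver contributions:

- **biomass**: ΔE/E = Σ_c w_c · ΔB_c/B_c, with biomass B_c from per-class
  NDVI regressions (classes: forest, agriculture, grassland);
- **temperature**: exp(β·ΔT) − 1, β = 0.1 per °C;
- **CO₂** (isoprene only, share ≈ 0.5): (C/C₀)^(−β_CO2) − 1,
  β_CO2 = 0.33;
- **soil moisture**: (SM − SM₀)/SM₀;
- **wildfire**: dry burnt biomass = area · forest fraction · density ·
  0.5, emission = dry mass · EF (g/kg), reported as event-scale rates.

The net anomaly is the sum of the four contributions plus an interaction
term, biomass × (sum of environmental contributions), equivalent to
(1 + biomass)(1 + env) − 1.  Per-driver error margins (3/3/10/20 %)
propagate to a half-width by linear sum or quadrature.

The package is aimed at ecosystem/atmosphere researchers who want this
attribution pipeline as tested, reusable code: it also covers
seasonal-amplitude analysis, per-pixel anomaly maps with mixing-length
smoothing, historical backcasts / scenario projections from temperature
and CO₂ trajectories, and a synthetic driver generator with known ground
truth so every stage is testable without downloads.

## Worked example

```r
library(bvocanom)

# per-driver contributions of the Germany 1979-2024 reference analysis
cs <- contribution_set(biomass = 0.24, temperature = 0.207,
                       co2 = 0.085, soil_moisture = -0.0528)
100 * combine_contributions(cs)
#> [1] 53.6608          # net anomaly, %: +53.66% since 1978
100 * propagate_errors(cs)
#> [1] 3.569            # linear-sum half-width, percentage points

100 * temperature_activity(1.88)        # +1.88 degC of warming
#> [1] 20.68335         # ~ +20.7% emission activity
100 * isoprene_to_total(co2_activity(0.62))
#> [1] 8.543778         # CO2 fell 38%: +8.5% total BVOC via isoprene

# wildfire calculus, Lueneburg Heath 1996 (4840 ha, 90% forest,
# 293 t/ha green biomass)
ev <- wildfire_event(4840, 0.9, 293)
dry <- wildfire_dry_biomass(ev)         # 638154 t ~ 0.638 million t dry
wildfire_emission(dry)
#> [1] 223.3539         # t of BVOC emitted
wildfire_rate(wildfire_emission(dry), 4840, 19.2)$ratio
#> [1] 9.244291         # ~9.2x the 0.26 kg/ha/day forest background
```

End-to-end on synthetic drivers:

```r
spec <- function(base, endpoint) gen_spec(1978, 2024, baseline = base,
                                          trend = endpoint / 46)
drv <- list(
  ndvi = list(forest = generate_driver_series(spec(0.6, 0.6 * 0.2502), "NDVI"),
              agriculture = generate_driver_series(spec(0.5, 0.5 * 0.281), "NDVI"),
              grassland = generate_driver_series(spec(0.5, 0.5 * 0.099), "NDVI")),
  temperature = generate_driver_series(spec(8, 1.88), "temperature"),
  co2 = generate_driver_series(spec(1, -0.38), "CO2"),
  soil_moisture = generate_driver_series(spec(25, -25 * 0.0528), "soil_moisture"))
s <- anomaly_series(drv, reference_year = 1978)
round(100 * s$values[s$years == 2024], 2)
#> [1] 53.74            # endpoint anomaly, %: the prescribed world recombined
piecewise_slopes(moving_average(s, 7), c(2005, 2020))
```

The `run_pipeline()` function (and `inst/cli/bvocanom.R`) exposes the
`simulate` / `attribute` / `seasonal` / `map` / `project` subcommands
around YAML configuration and plain-text CSV/JSON/`.asc` artifacts; see
`vignettes/bvoc-anomaly-attribution.Rmd` for the model, conventions and
limitations.

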