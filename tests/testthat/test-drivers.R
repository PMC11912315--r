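test_that("NDVI-to-biomass regression evaluates and guards its range", {
  m <- biomass_model(data.frame(class = "forest", intercept = 50,
                                slope = 400, ndvi_min = 0, ndvi_max = 1))
  expect_equal(ndvi_to_biomass(0.6, "forest", m), 290)
  m0 <- biomass_model(data.frame(class = "forest", intercept = 0,
                                 slope = 100, ndvi_min = 0, ndvi_max = 1))
  expect_equal(ndvi_to_biomass(0, "forest", m0), 0)
  # default forest model hits the temperate-forest density at peak NDVI
  expect_equal(ndvi_to_biomass(0.85, "forest"), 293, tolerance = 1e-12)
  expect_error(ndvi_to_biomass(0.5, "tundra"), "unknown class")
  expect_error(ndvi_to_biomass(1.2, "forest"), "range")
  mneg <- biomass_model(data.frame(class = "forest", intercept = -50,
                                   slope = 100, ndvi_min = 0, ndvi_max = 1))
  expect_warning(b <- ndvi_to_biomass(0.1, "forest", mneg), "clamped")
  expect_equal(b, 0)
})

test_that("area-weighted biomass contribution is linear and symmetric", {
  bc <- biomass_contribution(ref_biomass_parts / ref_class_weights,
                             ref_class_weights)
  expect_equal(bc$total, 0.2404, tolerance = 1e-9)
  expect_equal(bc$parts, ref_biomass_parts, tolerance = 1e-9)

  w <- c(a = 0.4, b = 0.6)
  expect_equal(biomass_contribution(c(a = 0, b = 0), w)$total, 0)
  expect_equal(biomass_contribution(c(x = 0.1), c(x = 1))$total, 0.1)
  expect_error(biomass_contribution(c(a = 0.1), w), "do not match")

  # linearity in each class change, invariance under permutation
  ch <- c(a = 0.2, b = -0.1)
  expect_equal(biomass_contribution(2 * ch, w)$total,
               2 * biomass_contribution(ch, w)$total)
  expect_equal(biomass_contribution(rev(ch), rev(w))$total,
               biomass_contribution(ch, w)$total)
})

test_that("temperature response reproduces the worked warming numbers", {
  expect_lt(abs(100 * temperature_activity(1.88, 0.1) - 20.7), 0.05)
  expect_equal(temperature_activity(0), 0)
  expect_lt(abs(100 * temperature_activity(0.5, 0.1) - 5.13), 0.005)
  # Q10 consistency: doubling needs beta = ln2/10; the conventional
  # beta = 0.1 gives a 10-degree factor of e instead
  expect_identical(temperature_activity(10, log(2) / 10), 1.0)
  expect_equal(temperature_activity(10, 0.1) + 1, exp(1))
  # monotone increasing, vanishing at the reference point
  dt <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(temperature_activity(dt)) > 0))
})

test_that("CO2 activity reproduces the worked isoprene numbers", {
  expect_lt(abs(100 * co2_activity(0.62, 0.33) - 17), 0.5)
  expect_equal(co2_activity(1), 0)
  expect_equal(co2_activity(0.5, 0), 0)
  expect_error(co2_activity(0), "positive")
  r <- seq(0.3, 2, by = 0.05)
  expect_true(all(diff(co2_activity(r)) < 0))

  expect_lt(abs(100 * isoprene_to_total(co2_activity(0.62, 0.33)) - 8.5),
            0.05)
  expect_equal(isoprene_to_total(0.17, 0), 0)
  expect_equal(isoprene_to_total(0.17, 1), 0.17)
})

test_that("soil-moisture contribution is the relative anomaly", {
  expect_equal(soil_moisture_contribution(25 * (1 - 0.0528), 25), -0.0528)
  expect_equal(soil_moisture_contribution(10, 10), 0)
  expect_equal(soil_moisture_contribution(20, 10), 1)
  expect_error(soil_moisture_contribution(5, 0), "positive")
})

test_that("wildfire calculus reproduces the Lueneburg Heath example", {
  ev <- wildfire_event(4840, 0.9, 293)
  dry <- wildfire_dry_biomass(ev, 0.5)
  expect_equal(dry, 638154)
  emitted <- wildfire_emission(dry)
  expect_lt(abs(emitted - 223.3), 0.1)
  r <- wildfire_rate(emitted, 4840, 19.2)
  expect_lt(abs(r$rate - 2.40), 0.01)
  expect_lt(abs(r$ratio - 9.24), 0.01)

  expect_equal(wildfire_dry_biomass(wildfire_event(0)), 0)
  expect_equal(wildfire_dry_biomass(wildfire_event(1, 1, 100), 0.5), 50)
  expect_equal(wildfire_emission(0), 0)
  expect_equal(wildfire_emission(1000, data.frame(value = 1, weight = 1)), 1)
  z <- wildfire_rate(0, 100, 10)
  expect_equal(c(z$rate, z$ratio), c(0, 0))
  expect_error(wildfire_rate(10, 0, 10), "positive")
})

test_that("wildfire pipeline is homogeneous of degree 1", {
  base <- wildfire_emission(wildfire_dry_biomass(wildfire_event(100, 0.8, 200)))
  for (k in c(2, 5)) {
    expect_equal(wildfire_emission(
      wildfire_dry_biomass(wildfire_event(100 * k, 0.8, 200))), k * base)
    expect_equal(wildfire_emission(
      wildfire_dry_biomass(wildfire_event(100, 0.8, 200 * k))), k * base)
  }
})

test_that("parameter containers validate their ranges", {
  expect_error(response_params(beta_t = -0.1), "beta_t")
  expect_error(response_params(isoprene_share = 1.5), "isoprene_share")
  expect_error(wildfire_event(-1), "area")
  expect_error(wildfire_event(1, emission_factors =
                                data.frame(value = 1, weight = 0.7)),
               "sum to 1")
})
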