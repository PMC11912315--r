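test_that("interaction term and combination reproduce the net anomaly", {
  expect_equal(interaction_term(0.24, c(0.207, 0.085, -0.0528)),
               0.24 * 0.2392)
  expect_equal(interaction_term(0, c(0.1, 0.2)), 0)
  expect_equal(interaction_term(0.3, c(0.1, -0.1)), 0)

  cs <- reference_contributions()
  expect_lt(abs(combine_contributions(cs) - 0.5366), 0.001)
  expect_equal(combine_contributions(cs, include_interaction = FALSE),
               0.4792)
  zero <- contribution_set(0, 0, 0, 0)
  expect_equal(combine_contributions(zero), 0)
  expect_error(contribution_set(NaN, 0, 0, 0), "finite")
})

test_that("combination with interaction equals the multiplicative expansion", {
  set.seed(1)
  for (i in 1:50) {
    b <- runif(1, -0.3, 0.5)
    e <- runif(3, -0.2, 0.3)
    cs <- contribution_set(b, e[1], e[2], e[3])
    expect_lt(abs(combine_contributions(cs) - ((1 + b) * (1 + sum(e)) - 1)),
              1e-12)
  }
})

test_that("error propagation follows linear-sum and quadrature rules", {
  cs <- reference_contributions()
  # arithmetic oracle: 0.03*0.24 + 0.03*0.207 + 0.10*0.0528 + 0.20*0.085
  expect_equal(propagate_errors(cs), 0.0072 + 0.00621 + 0.00528 + 0.017)
  expect_equal(propagate_errors(cs, method = "quadrature"),
               sqrt(0.0072^2 + 0.00621^2 + 0.00528^2 + 0.017^2))
  expect_equal(propagate_errors(cs, error_budget(0, 0, 0, 0)), 0)
  expect_error(propagate_errors(cs, method = "bootstrap"), "unknown")
  # the printed +-3.67 half-width is not derivable from the stated margins
  expect_false(abs(propagate_errors(cs) - 0.0367) < 0.001)
  expect_false(abs(propagate_errors(cs, method = "quadrature") - 0.0367) <
                 0.001)
})

test_that("moving_average matches the truncated-window oracle", {
  expect_equal(moving_average(c(0, 1, 2, 3, 4), 3), c(0.5, 1, 2, 3, 3.5))
  v <- rnorm(20)
  expect_equal(moving_average(v, 1), v)
  expect_equal(moving_average(rep(2, 10), 7), rep(2, 10))
  # commutes with adding a constant; idempotent on constants
  expect_equal(moving_average(v + 5, 4), moving_average(v, 4) + 5)
  cst <- moving_average(rep(1.5, 8), 4)
  expect_equal(moving_average(cst, 4), cst)
  expect_error(moving_average(v, 21), "exceeds")
})

test_that("piecewise slopes recover exact and noisy segment trends", {
  yrs <- 1987:2024
  exact <- cumsum(c(0, ifelse(yrs[-1] <= 2005, 0.024,
                              ifelse(yrs[-1] <= 2020, 0.006, -0.012))))
  s <- anomaly_series_new(yrs, exact - exact[1], reference_year = 1987)
  sl <- piecewise_slopes(s, c(2005, 2020))
  expect_equal(sl$slope_pct_per_yr, c(2.4, 0.6, -1.2), tolerance = 1e-9)

  flat <- anomaly_series_new(2000:2020, rep(0, 21))
  expect_true(all(piecewise_slopes(flat, 2010)$slope_pct_per_yr == 0))
  expect_error(piecewise_slopes(s, c(2022, 2023)), "fewer than 3")
})

test_that("anomaly_series reproduces prescribed endpoint contributions", {
  drv <- endpoint_drivers(cadence = 1)
  s <- anomaly_series(drv, reference_year = 1978)
  expect_equal(s$values[s$years == 1978], 0)
  truth <- endpoint_truth()
  last <- attr(s, "contributions")[length(s$years), ]
  # zero-noise parameter recovery to 1e-6
  expect_lt(abs(last$biomass - truth$biomass), 1e-6)
  expect_lt(abs(last$temperature - truth$temperature), 1e-6)
  expect_lt(abs(last$co2 - truth$co2), 1e-6)
  expect_lt(abs(last$soil_moisture - truth$soil_moisture), 1e-6)
  # the endpoint matches the combined reference contributions
  expect_lt(abs(s$values[length(s$values)] - 0.5366), 0.002)
})

test_that("constant drivers give an all-zero anomaly series", {
  mkconst <- function(base, kind) generate_driver_series(
    gen_spec(1978, 1990, baseline = base, seed = 1), kind)
  drv <- list(ndvi = mkconst(0.6, "NDVI"),
              temperature = mkconst(8, "temperature"),
              co2 = mkconst(1, "CO2"),
              soil_moisture = mkconst(25, "soil_moisture"))
  s <- anomaly_series(drv, reference_year = 1978)
  expect_true(all(abs(s$values) < 1e-12))
})

test_that("re-referencing renormalises multiplicatively", {
  drv <- endpoint_drivers(cadence = 1)
  s <- anomaly_series(drv, reference_year = 1978)
  s2 <- re_reference(s, 2024)
  expect_equal(s2$values[s2$years == 2024], 0)
  expect_equal(1 + s2$values, (1 + s$values) / (1 + s$values[length(s$values)]))
})

test_that("span mismatches are rejected naming the offending driver", {
  drv <- endpoint_drivers(cadence = 1)
  drv$temperature <- factor_series(1990:2024, rep(8, 35), "temperature")
  expect_error(anomaly_series(drv, reference_year = 1978),
               "reference year")
  expect_error(anomaly_series_new(2000:2005, c(0, 1, 2, 3, 4, 5),
                                  reference_year = 2001),
               "reference year must be 0")
})
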