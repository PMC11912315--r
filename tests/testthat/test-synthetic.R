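test_that("zero-noise generation is exactly the deterministic model curve", {
  spec <- gen_spec(1979, 2024, baseline = 8, trend = 0.04, seed = 5)
  fs <- generate_driver_series(spec, "temperature")
  expect_length(fs$values, 46)
  slope <- coef(lm(fs$values ~ fs$timestamps))[[2]]
  expect_equal(slope * 45, 1.80, tolerance = 1e-12)

  const <- generate_driver_series(
    gen_spec(2000, 2010, baseline = 0.6, seed = 1), "NDVI")
  expect_true(all(const$values == 0.6))

  seasonal <- gen_spec(2000, 2003, cadence = 12, baseline = 1,
                       seasonal_amplitude = 2,
                       seasonal_amplitude_trend = 0.1, seed = 1)
  fs2 <- generate_driver_series(seasonal, "temperature")
  expect_equal(fs2$values, spec_curve_for_test(seasonal), tolerance = 0)
})

test_that("invalid generator specs are rejected with a message", {
  expect_error(gen_spec(2000, 1990), "end_year")
  expect_error(gen_spec(2000, 2010, cadence = 0), "cadence")
  expect_error(gen_spec(2000, 2010, noise_sd = -1), "noise_sd")
  expect_error(generate_wildfire_events(-1, years = 2000:2010), "rate")
  expect_error(grid_spec(10, 10, c(forest = 0.5, other = 0.4)), "sum to 1")
})

test_that("fixed seed gives bit-identical output; streams are per-purpose", {
  spec <- gen_spec(1979, 2024, baseline = 0.6, trend = 0.001,
                   noise_sd = 0.02, seed = 42)
  a <- generate_driver_series(spec, "NDVI")
  b <- generate_driver_series(spec, "NDVI")
  expect_identical(a, b)

  ev1 <- generate_wildfire_events(2, 3, 1, years = 1979:2023, seed = 42)
  ev2 <- generate_wildfire_events(2, 3, 1, years = 1979:2023, seed = 42)
  expect_identical(ev1, ev2)

  # consuming the global RNG stream must not perturb generators
  set.seed(99); runif(3)
  expect_identical(generate_driver_series(spec, "NDVI"), a)
})

test_that("Monte-Carlo warming recovery matches the OLS expectation", {
  warm <- vapply(1:200, function(s) {
    spec <- gen_spec(1979, 2024, baseline = 8, trend = 1.88 / 45,
                     noise_sd = 0.3, seed = s)
    fs <- generate_driver_series(spec, "temperature")
    coef(lm(fs$values ~ fs$timestamps))[[2]] * 45
  }, numeric(1))
  expect_lt(abs(mean(warm) - 1.88), 0.05)
})

test_that("PFT grids honour exact class quotas and are deterministic", {
  g1 <- generate_pft_grid(grid_spec(10, 10, c(forest = 1), seed = 3))
  expect_true(all(g1$classes == "forest"))

  fr <- c(forest = 0.33, agriculture = 0.50, grassland = 0.12, other = 0.05)
  g <- generate_pft_grid(grid_spec(100, 100, fr, seed = 3))
  counts <- table(g$classes)[names(fr)]
  expect_true(all(abs(counts - fr * 10000) <= 1))

  g2 <- generate_pft_grid(grid_spec(100, 100, fr, seed = 3))
  expect_identical(g$classes, g2$classes)
})

test_that("gridded NDVI reduces to the class curves", {
  fr <- c(forest = 0.5, agriculture = 0.3, grassland = 0.2)
  pft <- generate_pft_grid(grid_spec(12, 12, fr, seed = 1))
  specs <- list(
    forest = gen_spec(2000, 2010, baseline = 0.6, trend = 0.002, seed = 1),
    agriculture = gen_spec(2000, 2010, baseline = 0.5, trend = 0.004,
                           seed = 1),
    grassland = gen_spec(2000, 2010, baseline = 0.5, trend = 0.001,
                         seed = 1))
  stack <- generate_gridded_ndvi(pft, specs)
  for (cl in names(fr)) {
    curve <- generate_driver_series(specs[[cl]], "NDVI")$values
    idx <- which(pft$classes == cl)
    sm <- apply(stack$values, 3, function(m) mean(m[idx]))
    expect_equal(sm, curve, tolerance = 1e-12)
  }
  expect_error(generate_gridded_ndvi(pft, specs["forest"]), "missing")

  # degenerate single-pixel grid
  p1 <- pft_grid(matrix("forest", 1, 1))
  s1 <- generate_gridded_ndvi(p1, list(forest = specs$forest))
  expect_equal(as.vector(s1$values),
               generate_driver_series(specs$forest, "NDVI")$values)
})

test_that("per-class trends are recovered from noisy gridded NDVI", {
  fr <- c(forest = 0.33, agriculture = 0.50, grassland = 0.12, other = 0.05)
  pft <- generate_pft_grid(grid_spec(80, 80, fr, seed = 7))
  trends <- c(forest = 0.001, agriculture = 0.002, grassland = 0.0003)
  specs <- lapply(names(fr), function(cl)
    gen_spec(1979, 2024, baseline = 0.5,
             trend = if (cl %in% names(trends)) trends[[cl]] else 0,
             noise_sd = 0.02, seed = 7))
  names(specs) <- names(fr)
  stack <- generate_gridded_ndvi(pft, specs, seed = 7)
  t <- stack$timestamps
  for (cl in names(trends)) {
    idx <- which(pft$classes == cl)
    sm <- apply(stack$values, 3, function(m) mean(m[idx]))
    slope <- coef(lm(sm ~ t))[[2]]
    expect_lt(abs(slope - trends[[cl]]) / trends[[cl]], 0.05)
  }
})

test_that("wildfire event generation follows the Poisson model", {
  expect_equal(nrow(generate_wildfire_events(0, years = 1979:2023)), 0)
  counts <- vapply(1:500, function(s)
    nrow(generate_wildfire_events(2, 3, 1, years = 1980:2024, seed = s)),
    numeric(1))
  expect_lt(abs(mean(counts) - 90), 0.5)
})
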