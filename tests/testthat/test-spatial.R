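test_that("pixel anomaly degenerates to the scalar pipeline", {
  fx <- uniform_spatial_fixture()
  field <- pixel_anomaly(fx$stack, fx$pft, fx$env, reference_year = 1978)
  scalar <- anomaly_series(
    c(list(ndvi = stats::setNames(list(
      generate_driver_series(fx$spec, "NDVI")), "forest")), fx$env),
    class_weights = c(forest = 1), reference_year = 1978)
  target <- scalar$values[length(scalar$values)]
  expect_true(all(abs(field$values - target) < 1e-12))
})

test_that("per-class field means equal per-class scalar results", {
  pft <- pft_grid(matrix(rep(c("forest", "agriculture"), each = 18), 6, 6))
  specs <- list(
    forest = gen_spec(1978, 1990, baseline = 0.6, trend = 0.003, seed = 2),
    agriculture = gen_spec(1978, 1990, baseline = 0.5, trend = 0.005,
                           seed = 2))
  stack <- generate_gridded_ndvi(pft, specs)
  env <- uniform_spatial_fixture()$env
  field <- pixel_anomaly(stack, pft, env, reference_year = 1978)
  for (cl in names(specs)) {
    scalar <- anomaly_series(
      c(list(ndvi = stats::setNames(
        list(generate_driver_series(specs[[cl]], "NDVI")), cl)), env),
      class_weights = stats::setNames(1, cl), reference_year = 1978)
    expect_lt(abs(mean(field$values[pft$classes == cl]) -
                    scalar$values[length(scalar$values)]), 1e-6)
  }
})

test_that("non-vegetated pixels are masked; geometry mismatch rejected", {
  fx <- uniform_spatial_fixture()
  other <- pft_grid(matrix("other", 6, 6))
  field <- pixel_anomaly(fx$stack, other, fx$env, reference_year = 1978)
  expect_true(all(is.na(field$values)))

  urban <- pft_grid(matrix("urban", 6, 6))
  fu <- pixel_anomaly(fx$stack, urban, fx$env, reference_year = 1978)
  expect_true(all(is.finite(fu$values)))  # urban carries a vegetated model

  small <- pft_grid(matrix("forest", 5, 5))
  expect_error(pixel_anomaly(fx$stack, small, fx$env), "geometry")
})

test_that("smoothing is the identity at radius 0 and on constants", {
  f <- grid_field(matrix(rnorm(100), 10, 10), pixel_size = 1000)
  expect_identical(smooth_field(f, 0), f)
  cf <- grid_field(matrix(3.5, 15, 15), pixel_size = 1000)
  for (r in c(1, 3, 7))
    expect_equal(smooth_field(cf, r)$values, cf$values, tolerance = 1e-12)
  expect_error(smooth_field(f, -1), "non-negative")
})

test_that("disc smoothing matches the brute-force convolution oracle", {
  v <- matrix(0, 21, 21)
  v[11, 11] <- 1
  f <- grid_field(v, pixel_size = 1000)
  r_px <- 3
  got <- smooth_field(f, 3)  # 3 km at 1000 m pixels = 3 px
  # independent brute force: per-pixel disc mean
  oracle <- matrix(NA_real_, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    acc <- c()
    for (a in 1:21) for (b in 1:21)
      if ((a - i)^2 + (b - j)^2 <= r_px^2) acc <- c(acc, v[a, b])
    oracle[i, j] <- mean(acc)
  }
  expect_equal(got$values, oracle, tolerance = 1e-12)
  # in-disc pixels around the spike all equal 1 / (disc pixel count)
  disc_n <- sum(outer((-3:3)^2, (-3:3)^2, "+") <= 9)
  expect_equal(got$values[11, 14], 1 / disc_n)
  expect_equal(got$values[8, 11], 1 / disc_n)
  expect_equal(got$values[11, 15], 0)
})

test_that("smoothing is linear, positivity-preserving and mass-conserving", {
  set.seed(4)
  a <- grid_field(matrix(runif(144), 12, 12), pixel_size = 1000)
  b <- grid_field(matrix(runif(144), 12, 12), pixel_size = 1000)
  sa <- smooth_field(a, 2)$values
  sb <- smooth_field(b, 2)$values
  sab <- smooth_field(grid_field(a$values + 2 * b$values,
                                 pixel_size = 1000), 2)$values
  expect_equal(sab, sa + 2 * sb, tolerance = 1e-12)
  expect_true(all(sa >= 0))
  # exact sum conservation on a periodic grid
  sw <- smooth_field(a, 2, wrap = TRUE)$values
  expect_equal(sum(sw), sum(a$values), tolerance = 1e-12)
})

test_that("masked pixels are excluded from numerator and denominator", {
  v <- matrix(1, 9, 9)
  v[5, 5] <- NA
  f <- grid_field(v, pixel_size = 1000)
  s <- smooth_field(f, 2)
  expect_true(is.na(s$values[5, 5]))
  expect_equal(s$values[-41], rep(1, 80))  # neighbours unaffected by the hole
})

test_that("gaussian kernel is selectable and mean-preserving inside", {
  set.seed(9)
  f <- grid_field(matrix(runif(400), 20, 20), pixel_size = 1000)
  s <- smooth_field(f, 3, kernel = "gaussian")
  expect_equal(dim(s$values), c(20, 20))
  expect_lt(abs(mean(s$values) - mean(f$values)) / abs(mean(f$values)),
            0.005)
})
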