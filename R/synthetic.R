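#' Specification of a synthetic driver series
#'
#' Describes the deterministic model curve and noise level for one
#' synthetic driver: a linear trend plus a single seasonal cosine harmonic
#' whose amplitude may itself drift linearly, plus iid Gaussian noise.
#' The seasonal harmonic peaks at mid-summer (year fraction 0.5).
#'
#' @param start_year,end_year calendar years, `end_year > start_year`.
#' @param cadence samples per year (integer >= 1).
#' @param baseline value at `start_year`, driver units.
#' @param trend linear trend, driver units per year.
#' @param seasonal_amplitude cosine amplitude at `start_year`, driver units
#'   (>= 0).
#' @param seasonal_amplitude_trend amplitude drift, driver units per year.
#' @param noise_sd standard deviation of iid Gaussian noise (>= 0).
#' @param seed integer seed; one seed spawns independent substreams for
#'   noise, grids and events, so adding a generator does not perturb others.
#' @return an object of class `gen_spec`.
#' @export
gen_spec <- function(start_year, end_year, cadence = 1L, baseline = 0,
                     trend = 0, seasonal_amplitude = 0,
                     seasonal_amplitude_trend = 0, noise_sd = 0, seed = 1L) {
  if (end_year <= start_year) stop("end_year must exceed start_year")
  cadence <- as.integer(cadence)
  if (is.na(cadence) || cadence < 1L) stop("cadence must be an integer >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (seasonal_amplitude < 0) stop("seasonal_amplitude must be non-negative")
  structure(list(start_year = start_year, end_year = end_year,
                 cadence = cadence, baseline = baseline, trend = trend,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_amplitude_trend = seasonal_amplitude_trend,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gen_spec")
}

#' Specification of a synthetic PFT grid
#'
#' @param n_rows,n_cols pixel counts.
#' @param pixel_size pixel edge length in metres (> 0); default 500 m
#'   mirrors the MODIS pixel size used for land-cover mapping.
#' @param class_fractions named numeric vector mapping PFT class to its
#'   areal fraction; fractions must lie in `[0, 1]` and sum to 1 within
#'   1e-9.  Class names come from [pft_classes()].
#' @param seed integer seed.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, class_fractions, pixel_size = 500,
                      seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (n_rows < 1 || n_cols < 1) stop("grid must have at least one pixel")
  f <- unlist(class_fractions)
  if (is.null(names(f)) || any(!nzchar(names(f))))
    stop("class_fractions must be named by PFT class")
  bad <- setdiff(names(f), pft_classes())
  if (length(bad))
    stop("unknown PFT class(es): ", paste(bad, collapse = ", "))
  if (any(f < 0) || any(f > 1)) stop("class fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) stop("class fractions must sum to 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = pixel_size, class_fractions = f,
                 seed = as.integer(seed)),
            class = "grid_spec")
}

## Deterministic per-purpose substream seed: one user seed spawns
## independent streams so generators do not perturb each other.
derive_seed <- function(seed, purpose) {
  h <- 0
  for (ch in utf8ToInt(purpose)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

## Run `expr` under a local RNG seeded with `seed`, restoring the caller's
## RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Time grid of a gen_spec: cadence points per year for every calendar
## year from start_year to end_year inclusive.
spec_times <- function(spec) {
  n <- (spec$end_year - spec$start_year + 1L) * spec$cadence
  spec$start_year + (seq_len(n) - 1L) / spec$cadence
}

## Deterministic (noise-free) model curve of a gen_spec.
spec_curve <- function(spec, t = spec_times(spec)) {
  dt <- t - spec$start_year
  amp <- spec$seasonal_amplitude + spec$seasonal_amplitude_trend * dt
  frac <- t - floor(t)
  spec$baseline + spec$trend * dt + amp * cos(2 * pi * (frac - 0.5))
}

#' Generate a synthetic driver time series
#'
#' Values follow `baseline + trend*(t - start) + (A + A_trend*(t - start)) *
#' cos(2*pi*(frac(t) - 0.5)) + N(0, noise_sd)`.  NDVI output is clipped to
#' `[-1, 1]` after noise; clipping events are reported via a message.
#' Output is bit-reproducible for a fixed seed.
#'
#' @param spec a [gen_spec()].
#' @param kind driver kind, see [factor_series()].
#' @return a [factor_series()].
#' @examples
#' s <- gen_spec(1979, 2024, baseline = 8, trend = 0.04, seed = 7)
#' fs <- generate_driver_series(s, "temperature")
#' coef(lm(fs$values ~ fs$timestamps))[[2]]  # recovers 0.04 exactly
#' @export
generate_driver_series <- function(spec, kind) {
  stopifnot(inherits(spec, "gen_spec"))
  kind <- match.arg(kind, driver_kinds())
  t <- spec_times(spec)
  v <- spec_curve(spec, t)
  if (spec$noise_sd > 0)
    v <- v + with_local_seed(derive_seed(spec$seed, "noise"),
                             stats::rnorm(length(t), 0, spec$noise_sd))
  if (kind == "NDVI") {
    n_clip <- sum(v < -1 | v > 1)
    if (n_clip > 0)
      message(sprintf("generate_driver_series: clipped %d NDVI value(s) to [-1, 1]",
                      n_clip))
    v <- pmin(1, pmax(-1, v))
  }
  units <- switch(kind, NDVI = "index", temperature = "degC",
                  CO2 = "ratio", soil_moisture = "kg/m2")
  factor_series(t, v, kind = kind, units = units)
}

#' Generate a categorical PFT grid
#'
#' Pixels are assigned to classes by exact quota on a sorted uniform random
#' field: target counts come from largest-remainder rounding of the
#' requested fractions, then pixels ranked by an iid uniform field are
#' filled class by class.  Realized counts therefore match the requested
#' fractions to within one pixel of rounding, and the spatial arrangement
#' is random but deterministic per seed.
#'
#' @param spec a [grid_spec()].
#' @return a [pft_grid()].
#' @export
generate_pft_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- spec$n_rows * spec$n_cols
  f <- spec$class_fractions
  counts <- largest_remainder(f * n)
  u <- with_local_seed(derive_seed(spec$seed, "grid"), stats::runif(n))
  ord <- order(u)
  labels <- rep(names(f), counts)
  cls <- character(n)
  cls[ord] <- labels
  pft_grid(matrix(cls, nrow = spec$n_rows, ncol = spec$n_cols),
           pixel_size = spec$pixel_size)
}

## Integer apportionment: floor, then distribute the remaining units to
## the largest fractional parts (ties broken by position).
largest_remainder <- function(x) {
  base <- floor(x)
  short <- round(sum(x)) - sum(base)
  if (short > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a gridded NDVI stack over a PFT grid
#'
#' Each pixel follows its class's [gen_spec()] curve with independent
#' Gaussian noise per pixel and time step.  At zero noise the per-class
#' spatial mean equals the class curve exactly.
#'
#' @param grid a [pft_grid()].
#' @param per_class_specs named list mapping every class present in `grid`
#'   to a [gen_spec()]; all specs must share the same time grid.
#' @param seed integer seed for the pixel-noise substream; defaults to the
#'   first spec's seed.
#' @return an object of class `gridded_series`: list with `values`
#'   (array `n_rows x n_cols x n_times`), `timestamps`, and `grid`.
#' @export
generate_gridded_ndvi <- function(grid, per_class_specs, seed = NULL) {
  stopifnot(inherits(grid, "pft_grid"))
  present <- setdiff(unique(as.vector(grid$classes)), NA_character_)
  missing <- setdiff(present, names(per_class_specs))
  if (length(missing))
    stop("missing gen_spec for class(es): ", paste(missing, collapse = ", "))
  specs <- per_class_specs[present]
  tg <- lapply(specs, spec_times)
  for (i in seq_along(tg)[-1])
    if (!isTRUE(all.equal(tg[[1]], tg[[i]])))
      stop("all per-class specs must share the same time grid")
  t <- tg[[1]]
  nt <- length(t)
  nr <- nrow(grid$classes); nc <- ncol(grid$classes)
  vals <- array(NA_real_, dim = c(nr, nc, nt))
  if (is.null(seed)) seed <- specs[[1]]$seed
  with_local_seed(derive_seed(seed, "gridded_ndvi"), {
    for (cls in present) {
      idx <- which(grid$classes == cls)        # pixel indices, column-major
      curve <- spec_curve(specs[[cls]], t)
      sd <- specs[[cls]]$noise_sd
      noise <- if (sd > 0)
        matrix(stats::rnorm(length(idx) * nt, 0, sd), length(idx), nt)
      else matrix(0, length(idx), nt)
      for (k in seq_len(nt))
        vals[idx + (k - 1L) * nr * nc] <- curve[k] + noise[, k]
    }
  })
  vals <- pmin(pmax(vals, -1), 1)  # argument order preserves dim
  structure(list(values = vals, timestamps = t, grid = grid, kind = "NDVI"),
            class = "gridded_series")
}

#' Generate synthetic wildfire events
#'
#' Event counts per year are Poisson(`rate_per_year`); burnt areas are
#' lognormal.  Deterministic per seed.
#'
#' @param rate_per_year expected events per year (>= 0).
#' @param area_log_mean,area_log_sd lognormal parameters of burnt area (ha).
#' @param years vector of calendar years to simulate.
#' @param seed integer seed.
#' @return data frame with columns `year` and `area_ha` (zero rows when
#'   `rate_per_year` is 0).
#' @export
generate_wildfire_events <- function(rate_per_year, area_log_mean = 3,
                                     area_log_sd = 1, years, seed = 1L) {
  if (rate_per_year < 0) stop("rate_per_year must be non-negative")
  with_local_seed(derive_seed(seed, "wildfire"), {
    counts <- stats::rpois(length(years), rate_per_year)
    year <- rep(years, counts)
    area <- stats::rlnorm(sum(counts), area_log_mean, area_log_sd)
    data.frame(year = year, area_ha = area)
  })
}
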