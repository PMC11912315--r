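#' Per-driver contribution set
#'
#' Holds the four per-driver fractional emission contributions, optional
#' per-class biomass parts and optional per-driver relative error margins.
#'
#' @param biomass,temperature,co2,soil_moisture fractional contributions.
#' @param biomass_parts optional named fractions per PFT class; must sum
#'   to `biomass` within 1e-9.
#' @param margins optional named non-negative relative margins (names from
#'   `biomass`, `temperature`, `co2`, `soil_moisture`).
#' @return an object of class `contribution_set`.
#' @export
contribution_set <- function(biomass, temperature, co2, soil_moisture,
                             biomass_parts = NULL, margins = NULL) {
  vals <- c(biomass = biomass, temperature = temperature, co2 = co2,
            soil_moisture = soil_moisture)
  if (any(!is.finite(vals)))
    stop("contributions must be finite; offending: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (!is.null(biomass_parts) &&
      abs(sum(biomass_parts) - biomass) > 1e-9)
    stop("per-class biomass parts must sum to the biomass total")
  if (!is.null(margins) && any(margins < 0))
    stop("margins must be non-negative")
  structure(list(biomass = biomass, temperature = temperature, co2 = co2,
                 soil_moisture = soil_moisture,
                 biomass_parts = biomass_parts, margins = margins),
            class = "contribution_set")
}

#' @export
print.contribution_set <- function(x, ...) {
  cat(sprintf(paste0("<contribution_set> biomass=%.4f temperature=%.4f ",
                     "co2=%.4f soil_moisture=%.4f\n"),
              x$biomass, x$temperature, x$co2, x$soil_moisture))
  invisible(x)
}

env_sum <- function(c) c$temperature + c$co2 + c$soil_moisture

#' Biomass-environment interaction term
#'
#' The environmental responses act on the *added* biomass as well as on the
#' reference biomass; to first order this cross effect is the product of
#' the biomass contribution and the summed environmental contributions.
#'
#' @param biomass_c biomass contribution, fraction.
#' @param env_contributions numeric vector of environmental contributions
#'   (temperature, CO2, soil moisture), fractions.
#' @return interaction contribution, fraction.
#' @examples
#' interaction_term(0.24, c(0.207, 0.085, -0.0528))  # 0.0574
#' @export
interaction_term <- function(biomass_c, env_contributions) {
  biomass_c * sum(env_contributions)
}

#' Combine per-driver contributions into the net anomaly
#'
#' Net anomaly = biomass + temperature + CO2 + soil moisture, plus (by
#' default) the biomass-environment [interaction_term()].  With the
#' interaction included the combination equals the exact first-order
#' product `(1 + biomass) * (1 + sum(env)) - 1`.
#'
#' @param c a [contribution_set()].
#' @param include_interaction include the interaction term?  Default TRUE.
#' @return net fractional anomaly.
#' @examples
#' cs <- contribution_set(0.24, 0.207, 0.085, -0.0528)
#' combine_contributions(cs)          # 0.5366
#' combine_contributions(cs, FALSE)   # 0.4792
#' @export
combine_contributions <- function(c, include_interaction = TRUE) {
  stopifnot(inherits(c, "contribution_set"))
  net <- c$biomass + env_sum(c)
  if (include_interaction)
    net <- net + interaction_term(c$biomass,
                                  c(c$temperature, c$co2, c$soil_moisture))
  net
}

#' Per-driver error budget
#'
#' Relative error margins per driver and the propagation method.  Defaults
#' reflect the robustness ranking of the drivers: biomass and temperature
#' are well constrained (3%), soil moisture is more variable (10%), and
#' CO2 carries the widest uncertainty (20%).
#'
#' @param biomass,temperature,soil_moisture,co2 relative margins (>= 0).
#' @param method `"linear_sum"` (default) or `"quadrature"`.
#' @return an object of class `error_budget`.
#' @export
error_budget <- function(biomass = 0.03, temperature = 0.03,
                         soil_moisture = 0.10, co2 = 0.20,
                         method = c("linear_sum", "quadrature")) {
  method <- match.arg(method)
  m <- c(biomass = biomass, temperature = temperature,
         soil_moisture = soil_moisture, co2 = co2)
  if (any(m < 0)) stop("margins must be non-negative")
  structure(list(margins = m, method = method), class = "error_budget")
}

#' Propagate per-driver margins to an anomaly half-width
#'
#' Each driver contributes an absolute half-width `|contribution| *
#' margin`.  Under `"linear_sum"` the half-widths add; under
#' `"quadrature"` they combine root-sum-square.  When
#' `include_interaction` is set, the first-order half-width of the
#' interaction term (`|sum(env)| * d_biomass + |biomass| * sum(d_env)`) is
#' added as one more component.
#'
#' @param c a [contribution_set()].
#' @param budget an [error_budget()].
#' @param method override of the budget's method.
#' @param include_interaction propagate through the interaction term too?
#'   Default FALSE (margins apply to the printed per-driver contributions).
#' @return half-width of the net anomaly, fraction.
#' @export
propagate_errors <- function(c, budget = error_budget(),
                             method = budget$method,
                             include_interaction = FALSE) {
  stopifnot(inherits(c, "contribution_set"), inherits(budget, "error_budget"))
  if (!method %in% c("linear_sum", "quadrature"))
    stop("unknown error-propagation method: ", method)
  m <- budget$margins
  contrib <- c(biomass = c$biomass, temperature = c$temperature,
               soil_moisture = c$soil_moisture, co2 = c$co2)
  if (any(!names(contrib) %in% names(m)))
    stop("budget must define a margin for every driver present")
  d <- abs(contrib) * m[names(contrib)]
  if (include_interaction) {
    d_env <- sum(d[c("temperature", "soil_moisture", "co2")])
    d_int <- abs(env_sum(c)) * d[["biomass"]] + abs(c$biomass) * d_env
    d <- c(d, interaction = d_int)
  }
  switch(method,
         linear_sum = sum(d),
         quadrature = sqrt(sum(d^2)))
}

#' Annual anomaly series relative to a reference year
#'
#' Container for a yearly fractional emission anomaly.  The value at the
#' reference year is 0 by construction (checked when the reference year is
#' inside the span).
#'
#' @param years calendar years, strictly increasing.
#' @param values fractional anomalies relative to `reference_year`.
#' @param reference_year the anomaly origin; default 1978, the year the
#'   long-term emission trend reversed.
#' @return an object of class `anomaly_series`.
#' @export
anomaly_series_new <- function(years, values, reference_year = 1978) {
  if (length(years) != length(values))
    stop("years and values must have the same length")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (reference_year %in% years &&
      abs(values[years == reference_year]) > 1e-12)
    stop("anomaly at the reference year must be 0")
  structure(list(years = as.numeric(years), values = as.numeric(values),
                 reference_year = reference_year),
            class = "anomaly_series")
}

#' @export
print.anomaly_series <- function(x, ...) {
  cat(sprintf("<anomaly_series> %d years (%d-%d), reference %s\n",
              length(x$years), min(x$years), max(x$years),
              format(x$reference_year)))
  invisible(x)
}

## annualised driver value per year, with a span check naming the driver
annual_or_stop <- function(fs, years, label) {
  am <- annual_means(fs)
  missing <- setdiff(years, as.numeric(names(am)))
  if (length(missing))
    stop(sprintf("driver '%s' does not cover year(s): %s", label,
                 paste(missing, collapse = ", ")))
  am[as.character(years)]
}

#' Assemble the anomaly series from driver time series
#'
#' Runs the full scalar attribution pipeline: drivers are annualised to
#' calendar-year means; each year's per-driver contribution is computed
#' relative to the reference year (biomass via the per-class NDVI
#' regression, temperature via [temperature_activity()], CO2 via
#' [co2_activity()] scaled by the isoprene share, soil moisture via
#' [soil_moisture_contribution()]); contributions are combined with
#' [combine_contributions()].
#'
#' @param drivers list with elements `ndvi` (a named list of per-class
#'   [factor_series()], or one series applied to all classes),
#'   `temperature`, `co2` and `soil_moisture` ([factor_series()]).  The
#'   CO2 series is interpreted as concentration (any units); ratios are
#'   formed against the reference year.
#' @param model a [biomass_model()].
#' @param params a [response_params()].
#' @param class_weights named non-negative area weights per PFT class.
#' @param reference_year anomaly origin; every driver must cover it.
#' @param include_interaction include the interaction term?  Default TRUE.
#' @return an `anomaly_series` whose attribute `"contributions"` is a data
#'   frame of the per-year per-driver contributions.
#' @export
anomaly_series <- function(drivers, model = default_biomass_model(),
                           params = response_params(),
                           class_weights = c(forest = 1 / 3,
                                             agriculture = 1 / 2,
                                             grassland = 1 / 6),
                           reference_year = 1978,
                           include_interaction = TRUE) {
  for (nm in c("temperature", "co2", "soil_moisture"))
    if (!inherits(drivers[[nm]], "factor_series"))
      stop("drivers$", nm, " must be a factor_series")
  ndvi <- drivers$ndvi
  if (inherits(ndvi, "factor_series"))
    ndvi <- stats::setNames(rep(list(ndvi), length(class_weights)),
                            names(class_weights))
  if (!setequal(names(ndvi), names(class_weights)))
    stop("ndvi classes must match class_weights")

  ## common span
  years_list <- lapply(c(ndvi, drivers[c("temperature", "co2",
                                         "soil_moisture")]),
                       function(fs) as.numeric(names(annual_means(fs))))
  years <- sort(Reduce(intersect, years_list))
  if (!reference_year %in% years)
    stop("drivers must cover the reference year ", reference_year)

  temp <- annual_or_stop(drivers$temperature, years, "temperature")
  co2 <- annual_or_stop(drivers$co2, years, "co2")
  sm <- annual_or_stop(drivers$soil_moisture, years, "soil_moisture")
  ndvi_y <- lapply(names(ndvi), function(cl)
    annual_or_stop(ndvi[[cl]], years, paste0("ndvi:", cl)))
  names(ndvi_y) <- names(ndvi)

  ref <- which(years == reference_year)
  b_ref <- vapply(names(ndvi_y), function(cl)
    ndvi_to_biomass(ndvi_y[[cl]][ref], cl, model), numeric(1))
  if (any(b_ref <= 0))
    stop("reference-year biomass must be positive for every class")
  sm0 <- sm[ref]
  if (sm0 <= 0) stop("reference-year soil moisture must be positive")

  n <- length(years)
  bio <- tmp <- cc <- smc <- net <- numeric(n)
  for (i in seq_len(n)) {
    ch <- vapply(names(ndvi_y), function(cl)
      ndvi_to_biomass(ndvi_y[[cl]][i], cl, model) / b_ref[[cl]] - 1,
      numeric(1))
    bio[i] <- biomass_contribution(ch, class_weights)$total
    tmp[i] <- temperature_activity(temp[i] - temp[ref], params$beta_t)
    cc[i] <- isoprene_to_total(co2_activity(co2[i] / co2[ref],
                                            params$beta_co2),
                               params$isoprene_share)
    smc[i] <- soil_moisture_contribution(sm[i], sm0)
    net[i] <- combine_contributions(
      contribution_set(bio[i], tmp[i], cc[i], smc[i]),
      include_interaction = include_interaction)
  }
  net[ref] <- 0  # exact by construction; guard against rounding
  out <- anomaly_series_new(years, net, reference_year)
  attr(out, "contributions") <- data.frame(
    year = years, biomass = bio, temperature = tmp, co2 = cc,
    soil_moisture = smc, net = net)
  out
}

#' Re-reference an anomaly series
#'
#' Multiplicative renormalisation to a new reference year:
#' `v' = (1 + v) / (1 + v[new_ref]) - 1`, so the new reference value is
#' exactly 0 and relative ratios between years are preserved.
#'
#' @param series an `anomaly_series`.
#' @param new_reference_year a year inside the series span.
#' @return an `anomaly_series` with the new reference.
#' @export
re_reference <- function(series, new_reference_year) {
  stopifnot(inherits(series, "anomaly_series"))
  i <- which(series$years == new_reference_year)
  if (length(i) != 1L)
    stop("new reference year must be inside the series span")
  v <- (1 + series$values) / (1 + series$values[i]) - 1
  v[i] <- 0
  anomaly_series_new(series$years, v, new_reference_year)
}

#' Centered moving average with shrinking edge windows
#'
#' Smooths a series with a centered window of `window` points.  Even
#' windows take one extra trailing point (offsets
#' `-floor((window-1)/2) .. +floor(window/2)`).  At the boundaries the
#' window shrinks instead of dropping years, so the output has the same
#' length and year axis as the input.
#'
#' @param series an `anomaly_series` or numeric vector.
#' @param window window length in years (>= 1, at most the series length).
#' @return smoothed object of the same type.
#' @export
moving_average <- function(series, window) {
  v <- if (inherits(series, "anomaly_series")) series$values else series
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  n <- length(v)
  if (window > n) stop("window exceeds series length")
  lo <- (window - 1L) %/% 2L
  hi <- window %/% 2L
  sm <- vapply(seq_len(n), function(i)
    mean(v[max(1L, i - lo):min(n, i + hi)]), numeric(1))
  if (inherits(series, "anomaly_series")) {
    out <- series
    out$values <- sm
    out
  } else sm
}

#' Piecewise OLS trend slopes
#'
#' Splits the series at the given breakpoint years (each breakpoint closes
#' the segment it ends, so breakpoints `c(2005, 2020)` give segments
#' `..-2005`, `2006-2020`, `2021-..`) and fits an ordinary least-squares
#' line per segment.
#'
#' @param series an `anomaly_series`.
#' @param breakpoints sorted years strictly inside the span.
#' @return data frame with columns `start`, `end`, `slope_pct_per_yr`.
#' @export
piecewise_slopes <- function(series, breakpoints = numeric(0)) {
  stopifnot(inherits(series, "anomaly_series"))
  yrs <- series$years
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be sorted and distinct")
  if (length(breakpoints) &&
      (min(breakpoints) < min(yrs) || max(breakpoints) >= max(yrs)))
    stop("breakpoints must lie strictly inside the series span")
  bounds <- c(min(yrs) - 1, breakpoints, max(yrs))
  out <- data.frame(start = numeric(0), end = numeric(0),
                    slope_pct_per_yr = numeric(0))
  for (k in seq_len(length(bounds) - 1L)) {
    sel <- yrs > bounds[k] & yrs <= bounds[k + 1L]
    if (sum(sel) < 3L)
      stop(sprintf("segment ending %s has fewer than 3 points",
                   format(bounds[k + 1L])))
    fit <- stats::lm(series$values[sel] ~ yrs[sel])
    out <- rbind(out, data.frame(start = min(yrs[sel]), end = max(yrs[sel]),
                                 slope_pct_per_yr = 100 * stats::coef(fit)[[2]]))
  }
  out
}
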