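#' Climate scenario trajectory
#'
#' A yearly trajectory of the two drivers that dominate BVOC emissions
#' outside the satellite era: the temperature offset relative to the
#' reference state and the CO2 concentration ratio relative to the
#' reference state.
#'
#' @param years calendar years, strictly increasing.
#' @param delta_t temperature offset vs reference, degC.
#' @param co2_ratio CO2 concentration ratio vs reference (> 0).
#' @param label free-text scenario label.
#' @return an object of class `scenario_trajectory`.
#' @export
scenario_trajectory <- function(years, delta_t, co2_ratio, label = "") {
  if (length(years) != length(delta_t) ||
      length(years) != length(co2_ratio))
    stop("years, delta_t and co2_ratio must have the same length")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (any(co2_ratio <= 0)) stop("co2_ratio must be positive")
  structure(list(years = as.numeric(years), delta_t = as.numeric(delta_t),
                 co2_ratio = as.numeric(co2_ratio), label = label),
            class = "scenario_trajectory")
}

## Single code path shared by reconstruct_history and project_future:
## per-year contribution set from (delta_t, co2_ratio) with proportional
## temperature-biomass coupling, combined as in the attribution module.
trajectory_anomaly <- function(traj, params, temp_biomass_coupling,
                               include_interaction = TRUE) {
  n <- length(traj$years)
  v <- numeric(n)
  for (i in seq_len(n)) {
    cs <- contribution_set(
      biomass = temp_biomass_coupling * traj$delta_t[i],
      temperature = temperature_activity(traj$delta_t[i], params$beta_t),
      co2 = isoprene_to_total(co2_activity(traj$co2_ratio[i],
                                           params$beta_co2),
                              params$isoprene_share),
      soil_moisture = 0)
    v[i] <- combine_contributions(cs, include_interaction)
  }
  v
}

#' Default temperature-biomass coupling
#'
#' Biomass is adjusted proportionally to the temperature offset when no
#' vegetation observations exist.  The default constant is calibrated
#' from the satellite era: a +24% biomass contribution accompanied a
#' +1.88 degC warming, i.e. 0.24 / 1.88 per degC.
#'
#' @return coupling constant, fraction per degC.
#' @export
default_temp_biomass_coupling <- function() 0.24 / 1.88

#' Reconstruct the pre-satellite anomaly history
#'
#' Extends the anomaly series backward from temperature and CO2
#' trajectories alone: per-year anomaly = temperature activity + CO2
#' induced total change + proportional biomass adjustment
#' (`coupling * delta_t`), combined exactly as in the attribution module.
#'
#' @param traj a [scenario_trajectory()].
#' @param params a [response_params()].
#' @param temp_biomass_coupling biomass fraction per degC of warming.
#' @param reference_year optional year to re-reference the output to
#'   (must lie inside the trajectory).  By default the trajectory's own
#'   reference state (`delta_t = 0`, `co2_ratio = 1`) defines the origin.
#' @return an `anomaly_series`.
#' @export
reconstruct_history <- function(traj, params = response_params(),
                                temp_biomass_coupling =
                                  default_temp_biomass_coupling(),
                                reference_year = NULL) {
  stopifnot(inherits(traj, "scenario_trajectory"))
  v <- trajectory_anomaly(traj, params, temp_biomass_coupling)
  ref <- if (is.null(reference_year)) NA_real_ else reference_year
  if (!is.null(reference_year)) {
    if (!reference_year %in% traj$years)
      stop("trajectory does not cover the requested reference year")
    i <- which(traj$years == reference_year)
    v <- (1 + v) / (1 + v[i]) - 1
    v[i] <- 0
  }
  anomaly_series_new(traj$years, v, reference_year = ref)
}

#' Detect the trend-reversal year
#'
#' Finds the year of the global minimum of the smoothed anomaly series.
#' Uncertainty is the half-width of the set of years whose smoothed value
#' lies within one noise standard deviation (estimated as the residual SD
#' of raw minus smoothed values) of the minimum.  A monotone series
#' returns its endpoint with a `"no interior minimum"` flag; exactly tied
#' minima farther apart than the uncertainty are flagged and the earliest
#' is returned.
#'
#' @param series an `anomaly_series`.
#' @param smoothing_window smoothing window in years (see
#'   [moving_average()]); must be smaller than the series length.
#' @return list with `year`, `uncertainty` (years), and `flag`
#'   (`NA_character_` when unremarkable).
#' @export
detect_reversal_year <- function(series, smoothing_window = 7) {
  stopifnot(inherits(series, "anomaly_series"))
  if (smoothing_window >= length(series$years))
    stop("series length must exceed the smoothing window")
  sm <- moving_average(series$values, smoothing_window)
  i <- which.min(sm)
  sigma <- stats::sd(series$values - sm)
  band <- series$years[sm <= sm[i] + sigma]
  unc <- (max(band) - min(band)) / 2
  flag <- NA_character_
  ties <- series$years[sm == sm[i]]
  if (length(ties) > 1 && (max(ties) - min(ties)) > unc)
    flag <- "multiple equal minima"
  if (i == 1L || i == length(sm))
    flag <- "no interior minimum"
  list(year = series$years[i], uncertainty = unc, flag = flag)
}

#' Project future emission anomalies
#'
#' Runs the scenario pipeline forward over the trajectory up to
#' `horizon_end` and summarises the projection as the OLS slope of the
#' anomaly in percent per year.
#'
#' @param traj a [scenario_trajectory()].
#' @param params a [response_params()].
#' @param horizon_end last projected year; the trajectory must reach it
#'   and start at or before it.
#' @param temp_biomass_coupling biomass fraction per degC; default 0 for
#'   pure climate-driven projections.
#' @return list with `series` (an `anomaly_series`),
#'   `rate_pct_per_yr` (OLS slope), and `label`.
#' @export
project_future <- function(traj, params = response_params(), horizon_end,
                           temp_biomass_coupling = 0) {
  stopifnot(inherits(traj, "scenario_trajectory"))
  if (horizon_end < min(traj$years))
    stop("horizon ends before the trajectory starts")
  if (horizon_end > max(traj$years))
    stop("trajectory does not cover the horizon")
  sel <- traj$years <= horizon_end
  sub <- scenario_trajectory(traj$years[sel], traj$delta_t[sel],
                             traj$co2_ratio[sel], traj$label)
  v <- trajectory_anomaly(sub, params, temp_biomass_coupling)
  series <- anomaly_series_new(sub$years, v, reference_year = NA_real_)
  rate <- 100 * stats::coef(stats::lm(v ~ sub$years))[[2]]
  list(series = series, rate_pct_per_yr = rate, label = traj$label)
}
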