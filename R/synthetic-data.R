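#' Configuration for the synthetic weather/mortality generator
#'
#' Defines a synthetic "city": a seasonal daily-maximum temperature-indicator
#' cycle with AR(1) noise, and daily Poisson mortality whose rate is a base
#' rate plus a magnitude-proportional excess on heatwave event + lag days.
#' Defaults emulate a Korean metropolis: seasonal mean
#' `a0 + a1 * sin(2*pi*(doy - phase)/365)` peaking near 30 degC on 1 August,
#' day-to-day persistence rho = 0.7 and innovation sd 3 degC for the daily
#' maxima, base mortality 10 per million per day and a population of one
#' million.
#'
#' @param n_years Number of years to simulate.
#' @param start_year First calendar year (default 2001).
#' @param a0,a1,phase Seasonal mean parameters (degC, degC, day of year).
#' @param rho AR(1) coefficient of the daily noise, in \[0, 1).
#' @param sigma Innovation standard deviation in degC, > 0.
#' @param tth_star True event threshold in degC.
#' @param l_star True lag length in days, in \[0, 14\].
#' @param alpha_star True excess-mortality slope (1e-6 per day), >= 0.
#' @param p0_star True base mortality rate (1e-6 per day), > 0.
#' @param population Population (constant, persons).
#' @param indicator Indicator label for generated series.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 30, start_year = 2001,
                             a0 = 16.5, a1 = 13.5, phase = 122,
                             rho = 0.7, sigma = 3,
                             tth_star = 33, l_star = 4,
                             alpha_star = 2, p0_star = 10,
                             population = 1e6, indicator = "Tmax",
                             seed = 1) {
  stopifnot(n_years >= 1, sigma > 0, rho >= 0, rho < 1,
            p0_star > 0, alpha_star >= 0, l_star >= 0, l_star <= 14,
            population > 0)
  structure(
    list(n_years = n_years, start_year = start_year, a0 = a0, a1 = a1,
         phase = phase, rho = rho, sigma = sigma, tth_star = tth_star,
         l_star = l_star, alpha_star = alpha_star, p0_star = p0_star,
         population = population, indicator = indicator,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

synthetic_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", config$start_year)),
      as.Date(sprintf("%d-12-31", config$start_year + config$n_years - 1)),
      by = "day")
}

seasonal_mean <- function(config, dates) {
  doy <- pmin(as.POSIXlt(dates)$yday + 1, 365)  # leap day folded onto day 365
  config$a0 + config$a1 * sin(2 * pi * (doy - config$phase) / 365)
}

#' Generate a synthetic daily indicator series
#'
#' Daily maxima `Tx(t) = mu(t) + e(t)` where `mu` is the seasonal cycle and
#' `e` is a stationary AR(1) process (`e_t = rho * e_{t-1} + N(0, sigma^2)`,
#' initialised from its stationary distribution). Deterministic for a fixed
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A [daily_series()].
#' @export
gen_indicator_series <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config", call. = FALSE)
  dates <- synthetic_dates(config)
  n <- length(dates)
  set.seed(config$seed)
  e <- numeric(n)
  sd_stat <- config$sigma / sqrt(1 - config$rho^2)
  e[1] <- stats::rnorm(1, 0, sd_stat)
  innov <- stats::rnorm(n - 1, 0, config$sigma)
  for (t in 2:n) e[t] <- config$rho * e[t - 1] + innov[t - 1]
  daily_series(dates, seasonal_mean(config, dates) + e,
               indicator = config$indicator)
}

#' Generate synthetic daily mortality for an indicator series
#'
#' Daily deaths are Poisson with mean `N * rate * 1e-6`, where the rate
#' (1e-6 per day) equals `p0_star` on ordinary days and
#' `p0_star + alpha_star * Mi` on every day of event i's event + lag window.
#' Events are defined from the series with the same extraction, magnitude and
#' lag-truncation code used on the fitting side, at the config's true
#' `tth_star` and `l_star`, so the generative and fitted windows coincide
#' exactly when the grid search lands on the truth.
#'
#' @param series A [daily_series()] (typically from [gen_indicator_series()]).
#' @param config A [synthetic_config()].
#' @return A [mortality_series()].
#' @export
gen_mortality <- function(series, config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must be a synthetic_config", call. = FALSE)
  n <- nrow(series)
  rate <- rep(config$p0_star, n)
  ev <- extract_events(series, config$tth_star, min_run = 3)
  ev <- assign_lag_windows(ev, config$l_star, n)
  for (i in seq_len(nrow(ev))) {
    evd <- seq.int(ev$start[i], ev$start[i] + ev$duration[i] - 1L)
    win <- seq.int(ev$start[i], ev$start[i] + ev$duration[i] + ev$lag[i] - 1L)
    mi <- event_magnitude(series$value[evd], config$tth_star)
    rate[win] <- config$p0_star + config$alpha_star * mi
  }
  # distinct stream from the weather noise: offset the seed deterministically
  set.seed((config$seed + 500081L) %% .Machine$integer.max)
  deaths <- stats::rpois(n, config$population * rate * 1e-6)
  mortality_series(series$date, deaths, config$population)
}

#' Generate a synthetic hourly meteorology stream
#'
#' Hourly records for exercising the thermal-index chain: a sinusoidal
#' diurnal air-temperature cycle around the seasonal daily mean (peak at
#' 15:00 local), relative humidity anticorrelated with temperature, constant
#' wind and cloud. Deterministic for a fixed config seed.
#'
#' @param config A [synthetic_config()].
#' @param n_days Number of days to generate (default 30).
#' @param diurnal_amplitude Half-range of the diurnal cycle in degC.
#' @param wind Constant wind speed in m/s.
#' @param cloud Constant cloud fraction in \[0, 1\].
#' @return Tibble with columns `timestamp`, `ta`, `rh`, `td`, `wind`,
#'   `cloud`, `tmrt` (td and tmrt left NA).
#' @export
gen_hourly_met <- function(config, n_days = 30, diurnal_amplitude = 4,
                           wind = 1.5, cloud = 0.3) {
  dates <- synthetic_dates(config)[seq_len(n_days)]
  ts <- as.POSIXct(paste(rep(dates, each = 24),
                         sprintf("%02d:00:00", 0:23)), tz = "UTC")
  mu_day <- rep(seasonal_mean(config, dates), each = 24)
  hour <- rep(0:23, n_days)
  set.seed((config$seed + 77003L) %% .Machine$integer.max)
  ta <- mu_day + diurnal_amplitude * cos(2 * pi * (hour - 15) / 24) +
    stats::rnorm(length(hour), 0, 0.3)
  rh <- pmin(100, pmax(20, 70 - 2.5 * (ta - mu_day) +
                         stats::rnorm(length(hour), 0, 2)))
  tibble::tibble(timestamp = ts, ta = ta, rh = rh, td = NA_real_,
                 wind = wind, cloud = cloud, tmrt = NA_real_)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a synthetic dataset, runs the full grid search, and
#' compares the recovered (Tth, L, alpha, p0) against the generating truth.
#' Seeds for replicate s are derived deterministically from the config seed.
#'
#' @param config A [synthetic_config()] holding the truth.
#' @param n_seeds Number of independent replicates, >= 1.
#' @param grid A [grid_spec()].
#' @return Tibble of class `recovery_report`, one row per replicate:
#'   `seed`, `tth_hat`, `l_hat`, `alpha_hat`, `p0_hat`, `r2`, `p_value`,
#'   `n_events`, plus error columns `tth_err`, `l_err`, `alpha_ratio`,
#'   `p0_ratio`.
#' @export
recovery_experiment <- function(config, n_seeds = 20, grid = grid_spec()) {
  stopifnot(n_seeds >= 1)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- (config$seed + 1000L * s) %% .Machine$integer.max
    ser <- gen_indicator_series(cfg)
    mort <- gen_mortality(ser, cfg)
    fit <- grid_search(ser, mort, grid)
    rows[[s]] <- tibble::tibble(
      seed = cfg$seed, tth_hat = fit$tth, l_hat = fit$lag,
      alpha_hat = fit$alpha, p0_hat = fit$p0, r2 = fit$r2,
      p_value = fit$p_value, n_events = fit$n_events)
  }
  out <- dplyr::bind_rows(rows)
  out$tth_err <- out$tth_hat - config$tth_star
  out$l_err <- out$l_hat - config$l_star
  out$alpha_ratio <- if (config$alpha_star > 0)
    out$alpha_hat / config$alpha_star else NA_real_
  out$p0_ratio <- out$p0_hat / config$p0_star
  class(out) <- c("recovery_report", class(out))
  attr(out, "truth") <- config[c("tth_star", "l_star", "alpha_star", "p0_star")]
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf(
    paste0("<recovery_report> %d replicates; truth Tth = %g, L = %g, ",
           "alpha = %g, p0 = %g\n  median |Tth err| = %g degC, ",
           "median |L err| = %g d\n"),
    nrow(x), tr$tth_star, tr$l_star, tr$alpha_star, tr$p0_star,
    stats::median(abs(x$tth_err)), stats::median(abs(x$l_err))))
  NextMethod()
}
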