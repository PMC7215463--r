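#' Estimated total mortality of one event
#'
#' Predicted deaths over one event + lag window from a fitted model:
#' `N-hat = Ni * (Mi * alpha + p0) * 1e-6 * (Di + Li)`, where `alpha` and `p0`
#' are in 1e-6 per day so the factor 1e-6 converts the modelled rate to a raw
#' per-person daily rate before multiplying by person-days. Negative predicted
#' totals (possible when the fitted line dips below zero at small magnitudes)
#' are returned as-is with a warning so residual diagnostics stay honest.
#'
#' @param magnitude Event magnitude Mi.
#' @param alpha Fitted slope (1e-6 per day per unit magnitude).
#' @param p0 Fitted base rate (1e-6 per day).
#' @param population Mean population Ni over the event + lag window.
#' @param window_days Window length Di + Li in days.
#' @return Expected deaths (may be fractional).
#' @export
estimate_event_mortality <- function(magnitude, alpha, p0, population,
                                     window_days) {
  est <- population * (magnitude * alpha + p0) * 1e-6 * window_days
  if (any(est < 0))
    warning("negative predicted event mortality (reported unclipped)")
  est
}

#' Root-mean-square error
#'
#' @param observed,estimated Equal-length numeric vectors.
#' @return `sqrt(mean((observed - estimated)^2))`.
#' @export
rmse <- function(observed, estimated) {
  if (length(observed) == 0L || length(observed) != length(estimated))
    stop("`observed` and `estimated` must be non-empty and of equal length",
         call. = FALSE)
  sqrt(mean((observed - estimated)^2))
}

#' Normalised root-mean-square error
#'
#' RMSE divided by the mean observed value, so models with different event
#' counts and scales can be compared; invariant under a common rescaling of
#' both vectors.
#'
#' @inheritParams rmse
#' @return `rmse(observed, estimated) / mean(observed)`.
#' @export
nrmse <- function(observed, estimated) {
  m <- mean(observed)
  if (!is.finite(m) || m <= 0)
    stop("mean of `observed` must be positive", call. = FALSE)
  rmse(observed, estimated) / m
}

#' Annual mean excess mortality rate
#'
#' Person-time-weighted excess mortality accrued per year under the fitted
#' model, by the convention `MEMR = sum_i Mi * alpha * (Di + Li) / n_years`
#' in 1e-6 per year. (The exact aggregation behind published MEMR tables is
#' not standardised; this convention is linear in alpha and proportional to
#' the excess person-days, and is labelled as such in all output.)
#'
#' @param events Per-event table (from [event_table()] or a `heat_fit`).
#' @param alpha Fitted slope in 1e-6 per day.
#' @param n_years Number of years spanned by the events' period; >= 1.
#' @return MEMR in 1e-6 per year.
#' @export
annual_memr <- function(events, alpha, n_years) {
  if (!is.finite(n_years) || n_years <= 0)
    stop("`n_years` must be positive", call. = FALSE)
  if (nrow(events) == 0L) return(0)
  sum(events$magnitude * alpha * (events$duration + events$lag)) / n_years
}

#' Score a fitted model on one period's events
#'
#' @param events Per-event table for the period.
#' @param fit A `heat_fit` (or any list with `alpha`, `p0`).
#' @param period Label, `"train"` or `"test"`.
#' @return A tibble row: period, n_events, rmse, nrmse; plus the per-event
#'   observed/estimated totals as an attribute `"per_event"`.
#' @export
score_events <- function(events, fit, period = "train") {
  if (nrow(events) == 0L) {
    out <- tibble::tibble(period = period, n_events = 0L,
                          rmse = NA_real_, nrmse = NA_real_)
    attr(out, "per_event") <- tibble::tibble(
      event_start = as.Date(character(0)), duration = integer(0),
      lag = integer(0), magnitude = numeric(0), observed = numeric(0),
      estimated = numeric(0))
    return(out)
  }
  est <- estimate_event_mortality(events$magnitude, fit$alpha, fit$p0,
                                  events$mean_population,
                                  events$duration + events$lag)
  out <- tibble::tibble(period = period, n_events = nrow(events),
                        rmse = rmse(events$observed_deaths, est),
                        nrmse = nrmse(events$observed_deaths, est))
  attr(out, "per_event") <- tibble::tibble(
    event_start = events$date, duration = events$duration, lag = events$lag,
    magnitude = events$magnitude, observed = events$observed_deaths,
    estimated = est)
  out
}

#' Chronological train/test evaluation
#'
#' Fits the model by grid search on years up to and including `split_year`,
#' freezes the selected (Tth, L, alpha, p0), extracts test-period events with
#' the frozen threshold and lag, and scores observed vs estimated per-event
#' total mortality in both periods. A test period with no exceedance events
#' yields an empty (NA-scored) test row, not an error.
#'
#' @param series A [daily_series()].
#' @param mortality A [mortality_series()] aligned with `series`.
#' @param grid A [grid_spec()].
#' @param split_year Last calendar year of the training period.
#' @return List with `fit` (the training `heat_fit`), `scores` (two-row
#'   tibble, train and test), `train_events`, `test_events`, and
#'   `train_memr` (annual MEMR over the training years).
#' @export
train_test_evaluate <- function(series, mortality, grid = grid_spec(),
                                split_year) {
  yr <- as.integer(format(series$date, "%Y"))
  if (split_year < min(yr) || split_year >= max(yr))
    stop("`split_year` must fall strictly inside the data span", call. = FALSE)
  tr <- yr <= split_year
  tr_series <- daily_series(series$date[tr], series$value[tr],
                            indicator_name(series))
  tr_mort <- mortality_series(mortality$date[tr], mortality$deaths[tr],
                              mortality$population[tr],
                              region = attr(mortality, "region"),
                              age = attr(mortality, "age"))
  te_series <- daily_series(series$date[!tr], series$value[!tr],
                            indicator_name(series))
  te_mort <- mortality_series(mortality$date[!tr], mortality$deaths[!tr],
                              mortality$population[!tr],
                              region = attr(mortality, "region"),
                              age = attr(mortality, "age"))

  fit <- grid_search(tr_series, tr_mort, grid)
  test_events <- event_table(te_series, te_mort, fit$tth, fit$lag,
                             min_run = grid$min_run)
  scores <- dplyr::bind_rows(
    score_events(fit$events, fit, "train"),
    score_events(test_events, fit, "test"))
  n_train_years <- length(unique(yr[tr]))
  list(fit = fit, scores = scores,
       train_events = fit$events, test_events = test_events,
       train_memr = annual_memr(fit$events, fit$alpha, n_train_years))
}
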