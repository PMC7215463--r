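#' Daily temperature-indicator series
#'
#' A tibble of consecutive calendar days with the daily maximum of one
#' temperature indicator. Missing daily values are allowed (NA) and break
#' consecutive-day runs during event extraction.
#'
#' @param dates Vector of `Date`s, strictly increasing by one day.
#' @param values Numeric daily maxima in degC (NA = missing day).
#' @param indicator Indicator name, one of `"PTmax"`, `"Tmax"`, `"WBGTmax"`
#'   (other labels are accepted for synthetic indicators).
#' @return A tibble of class `daily_series` with columns `date`, `value`.
#' @export
daily_series <- function(dates, values, indicator = "Tmax") {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty series", call. = FALSE)
  if (length(dates) != length(values))
    stop("`dates` and `values` must have equal length", call. = FALSE)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("`dates` must be consecutive calendar days", call. = FALSE)
  if (any(is.infinite(values)))
    stop("`values` must be finite or NA", call. = FALSE)
  out <- tibble::tibble(date = dates, value = as.numeric(values))
  attr(out, "indicator") <- indicator
  class(out) <- c("daily_series", class(out))
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s, %d days (%s to %s), %d missing\n",
              attr(x, "indicator"), nrow(x), format(min(x$date)),
              format(max(x$date)), sum(is.na(x$value))))
  NextMethod()
}

#' Indicator name of a daily series
#' @param x A `daily_series`.
#' @return The indicator label.
#' @export
indicator_name <- function(x) attr(x, "indicator")

#' Daily mortality series for one stratum
#'
#' Daily death counts and population for a region x age-group stratum. The
#' daily all-cause mortality rate is carried in units of 1e-6 per day:
#' `rate = deaths / population * 1e6`.
#'
#' @param dates Vector of `Date`s, strictly increasing by one day.
#' @param deaths Non-negative integer daily death counts (NA = missing).
#' @param population Positive daily population (annual counts interpolated to
#'   days upstream; a scalar is recycled).
#' @param region,age Stratum labels (age conventionally one of `"0-64"`,
#'   `"65+"`, `"all"`).
#' @return A tibble of class `mortality_series` with columns `date`, `deaths`,
#'   `population`, `rate`.
#' @export
mortality_series <- function(dates, deaths, population, region = "all", age = "all") {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty series", call. = FALSE)
  population <- rep_len(population, length(dates))
  if (length(deaths) != length(dates))
    stop("`deaths` must match `dates` in length", call. = FALSE)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("`dates` must be consecutive calendar days", call. = FALSE)
  if (any(deaths < 0, na.rm = TRUE))
    stop("`deaths` must be non-negative", call. = FALSE)
  if (any(!is.finite(population) | population <= 0))
    stop("`population` must be positive and finite", call. = FALSE)
  out <- tibble::tibble(
    date = dates,
    deaths = as.numeric(deaths),
    population = as.numeric(population),
    rate = as.numeric(deaths) / as.numeric(population) * 1e6
  )
  attr(out, "region") <- region
  attr(out, "age") <- age
  class(out) <- c("mortality_series", class(out))
  out
}

#' @export
print.mortality_series <- function(x, ...) {
  cat(sprintf("<mortality_series> %s / %s, %d days, mean rate %.2f x 1e-6/day\n",
              attr(x, "region"), attr(x, "age"), nrow(x),
              mean(x$rate, na.rm = TRUE)))
  NextMethod()
}

#' Stratum labels of a mortality series
#' @param x A `mortality_series`.
#' @return Named character vector with `region` and `age`.
#' @export
stratum <- function(x) c(region = attr(x, "region"), age = attr(x, "age"))

#' Daily maxima of an hourly indicator
#'
#' Reduces a timestamped hourly series to per-day maxima. A calendar day with
#' fewer than `min_hours` valid (non-missing) hourly values is marked missing,
#' so sparse days cannot contribute a spuriously low maximum. Input order does
#' not matter. Days absent from the input within the spanned range are
#' missing.
#'
#' @param timestamps POSIXct timestamps (local civil time).
#' @param values Hourly indicator values (NA = invalid hour).
#' @param indicator Indicator label for the result.
#' @param min_hours Minimum valid hours for a day to count (default 18 of 24).
#' @return A [daily_series()] spanning the full date range of the input.
#' @export
daily_max <- function(timestamps, values, indicator = "Tmax", min_hours = 18) {
  if (length(timestamps) == 0L) stop("empty input", call. = FALSE)
  if (length(timestamps) != length(values))
    stop("`timestamps` and `values` must have equal length", call. = FALSE)
  day <- as.Date(timestamps, tz = attr(as.POSIXlt(timestamps[1]), "tzone")[1] %||% "")
  all_days <- seq(min(day), max(day), by = "day")
  valid <- !is.na(values)
  n_valid <- vapply(all_days, function(d) sum(valid[day == d]), numeric(1))
  vmax <- vapply(seq_along(all_days), function(i) {
    if (n_valid[i] >= min_hours)
      max(values[day == all_days[i]], na.rm = TRUE)
    else NA_real_
  }, numeric(1))
  daily_series(all_days, vmax, indicator = indicator)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate annual population to daily values
#'
#' Annual population releases are mapped to a daily series by linear
#' interpolation between mid-years (constant extrapolation at the ends), so
#' event-window mean populations vary smoothly rather than jumping at
#' year boundaries.
#'
#' @param years Integer years.
#' @param population Annual population counts (same length as `years`).
#' @param dates Dates at which daily values are needed.
#' @return Numeric vector of daily population, one per date.
#' @export
interpolate_population <- function(years, population, dates) {
  stopifnot(length(years) == length(population), length(years) >= 1)
  if (length(years) == 1L) return(rep(population, length(dates)))
  mid <- as.numeric(as.Date(paste0(years, "-07-01")))
  x <- as.numeric(as.Date(dates))
  stats::approx(mid, population, xout = x, rule = 2)$y
}
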