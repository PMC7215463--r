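#' Read an hourly meteorology CSV
#'
#' Expects columns `timestamp,ta,rh,td,wind,cloud,tmrt` (ISO-8601 timestamps;
#' empty cells are missing). Rows violating basic physical ranges
#' (RH outside \[0, 100\], negative wind, dew point above air temperature) are
#' dropped with a warning reporting the count.
#'
#' @param path Path to the CSV file.
#' @param tz Time zone of the timestamps (default `"UTC"`).
#' @return Tibble of validated hourly records.
#' @export
read_met_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "ta", "rh", "td", "wind", "cloud", "tmrt")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = tz)
  for (v in c("ta", "rh", "td", "wind", "cloud", "tmrt"))
    df[[v]] <- as.numeric(df[[v]])
  bad <- (!is.na(df$rh) & (df$rh < 0 | df$rh > 100)) |
    (!is.na(df$wind) & df$wind < 0) |
    (!is.na(df$td) & !is.na(df$ta) & df$td > df$ta) |
    is.na(df$timestamp)
  if (any(bad))
    warning(sprintf("dropped %d row(s) failing range validation", sum(bad)))
  tibble::as_tibble(df[!bad, need])
}

#' Write a daily indicator series to CSV
#'
#' Columns `date,indicator,value`.
#'
#' @param series A [daily_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path) {
  utils::write.csv(
    data.frame(date = format(series$date), indicator = indicator_name(series),
               value = series$value),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily indicator series from CSV
#'
#' Inverse of [write_daily_csv()] (columns `date,indicator,value`).
#'
#' @param path Path to the CSV file.
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_series(as.Date(df$date), df$value,
               indicator = df$indicator[1] %||% "Tx")
}

#' Read a joined daily indicator + mortality CSV
#'
#' Columns `date,tx,deaths,population`; returns the aligned pair of series
#' used by the fitting functions.
#'
#' @param path Path to the CSV file.
#' @param indicator Indicator label for the temperature column.
#' @param region,age Stratum labels for the mortality series.
#' @return List with elements `series` ([daily_series()]) and `mortality`
#'   ([mortality_series()]).
#' @export
read_joined_csv <- function(path, indicator = "Tmax", region = "all",
                            age = "all") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tx", "deaths", "population")
  if (!all(need %in% names(df)))
    stop("joined CSV needs columns date,tx,deaths,population", call. = FALSE)
  dates <- as.Date(df$date)
  list(series = daily_series(dates, df$tx, indicator = indicator),
       mortality = mortality_series(dates, df$deaths, df$population,
                                    region = region, age = age))
}

#' Read a run configuration from YAML
#'
#' Reads grid settings, the train/test split year and any synthetic-city
#' definitions into the list consumed by [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
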