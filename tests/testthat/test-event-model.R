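make_series <- function(values, start = "2010-06-01", indicator = "Tmax") {
  daily_series(seq(as.Date(start), by = "day", length.out = length(values)),
               values, indicator = indicator)
}

make_mortality <- function(deaths, population = 1e6, start = "2010-06-01") {
  mortality_series(seq(as.Date(start), by = "day", length.out = length(deaths)),
                   deaths, population)
}

test_that("event extraction finds maximal runs of strict exceedance", {
  expect_equal(extract_events(c(30, 33, 33, 33, 30), 32),
               tibble::tibble(start = 2L, duration = 3L))
  # two runs of length 2: no events
  expect_equal(nrow(extract_events(c(33, 33, 30, 33, 33), 32)), 0L)
  # equality does not exceed; missing days break runs
  expect_equal(nrow(extract_events(c(32, 32, 32, 32), 32)), 0L)
  expect_equal(nrow(extract_events(c(33, 33, NA, 33, 33, 33), 32)), 1L)
  expect_error(extract_events(numeric(0), 30), "empty")
})

test_that("event extraction agrees with brute-force enumeration", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(10:60, 1)
    x <- round(rnorm(n, 31, 2), 1)
    x[sample(n, floor(n / 10))] <- NA
    tth <- sample(c(29, 30, 31, 32), 1)
    got <- extract_events(x, tth)
    want <- oracle_extract_events(x, tth)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("event magnitude is log10 of one plus the summed exceedance", {
  expect_equal(event_magnitude(c(35, 35, 35), 32), 1)
  expect_equal(event_magnitude(c(33, 33, 33), 32), log10(4))
  # vanishing exceedance gives vanishing magnitude
  expect_equal(event_magnitude(rep(32 + 1e-9, 3), 32), 0, tolerance = 1e-8)
  expect_error(event_magnitude(c(33, 32, 33), 32), "exceed")
  # strictly increasing in any one day's exceedance
  m <- vapply(seq(0.1, 3, by = 0.1),
              function(d) event_magnitude(c(33, 33, 33 + d), 32), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("lag windows are truncated at the next event and the series end", {
  # single event ending well before the end keeps its full lag
  ev <- tibble::tibble(start = 5L, duration = 3L)
  expect_equal(assign_lag_windows(ev, 5, 30)$lag, 5L)
  # event A ends day 10, event B starts day 13: A's lag truncates to 2
  ev2 <- tibble::tibble(start = c(8L, 13L), duration = c(3L, 4L))
  expect_equal(assign_lag_windows(ev2, 5, 40)$lag, c(2L, 5L))
  # event ending on the last day gets no lag
  ev3 <- tibble::tibble(start = 28L, duration = 3L)
  expect_equal(assign_lag_windows(ev3, 5, 30)$lag, 0L)
  # adjacent events: zero gap, zero lag
  ev4 <- tibble::tibble(start = c(1L, 4L), duration = c(3L, 3L))
  expect_equal(assign_lag_windows(ev4, 7, 6)$lag, c(0L, 0L))
})

test_that("event windows are disjoint and fit inside the series", {
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(30:100, 1)
    x <- rnorm(n, 31, 2.5)
    ev <- extract_events(x, 31)
    ev <- assign_lag_windows(ev, sample(0:14, 1), n)
    if (nrow(ev) == 0) next
    expect_lte(sum(ev$duration + ev$lag), n)
    days <- unlist(mapply(function(s, d, l) seq.int(s, s + d + l - 1L),
                          ev$start, ev$duration, ev$lag, SIMPLIFY = FALSE))
    expect_false(any(duplicated(days)))
    expect_lte(max(days), n)
  }
})

test_that("event-mean mortality averages daily rates over event + lag days", {
  mort <- make_mortality(rep(2, 10))
  # constant rate: the mean is that rate
  expect_equal(event_mean_mortality(mort, 3, 3, 2), 2 / 1e6 * 1e6)
  # hand-computed mean over a 4-day window
  m2 <- make_mortality(c(10, 20, 30, 40), population = 1e6)
  expect_equal(event_mean_mortality(m2, 1, 3, 1), 25)
  # unit bookkeeping: 1 death/day in a million-person city = 1 per 1e-6/day
  m3 <- make_mortality(c(1, 1, 1))
  expect_equal(event_mean_mortality(m3, 1, 3, 0), 1)
  expect_error(event_mean_mortality(m3, 2, 3, 0), "outside")
})

test_that("missing mortality is only tolerated where the indicator is missing too", {
  deaths <- c(5, 5, NA, 5, 5)
  mort <- make_mortality(replace(rep(5, 5), 3, NA))
  ind_ok <- c(34, 34, NA, 30, 30)      # indicator missing on the same day
  ind_bad <- c(34, 34, 30, 30, 30)     # indicator observed on the NA day
  expect_equal(event_mean_mortality(mort, 1, 2, 2, ind_ok), 5)
  expect_error(event_mean_mortality(mort, 1, 2, 2, ind_bad), "observed")
  expect_error(event_mean_mortality(mort, 1, 2, 2), "missing mortality")
})

test_that("OLS regression matches the closed-form normal equations", {
  # exact line: perfect fit
  m <- c(0.2, 0.5, 1.1, 1.4)
  fit <- fit_event_regression(m, 2 * m + 10)
  expect_equal(fit$alpha, 2, tolerance = 1e-12)
  expect_equal(fit$p0, 10, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # frozen three-point case, closed form evaluated by hand
  fit3 <- fit_event_regression(c(0.5, 1.0, 1.5), c(11, 12, 14))
  expect_equal(fit3$alpha, 3, tolerance = 1e-12)
  expect_equal(fit3$p0, 28 / 3, tolerance = 1e-12)
  expect_equal(fit3$r2, 27 / 28, tolerance = 1e-12)
  # random instances against the independent normal-equations oracle
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- 1.5 * x + rnorm(n)
    got <- fit_event_regression(x, y)
    want <- oracle_ols(x, y)
    expect_equal(got$alpha, want$slope, tolerance = 1e-10)
    expect_equal(got$p0, want$intercept, tolerance = 1e-10)
    expect_equal(got$r2, want$r2, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  }
})

test_that("regression refuses degenerate inputs", {
  expect_error(fit_event_regression(c(1, 2), c(3, 4)),
               class = "heatmort_unfit")
  expect_error(fit_event_regression(c(1, 1, 1), c(3, 4, 5)),
               class = "heatmort_unfit")
})

test_that("significance tiers follow the 95/90/85% star convention", {
  expect_equal(significance_tier(c(0.04, 0.05, 0.08, 0.12, 0.15, 0.5)),
               c("***", "***", "**", "*", "*", "NS"))
  expect_error(significance_tier(1.2), "0, 1")
  expect_error(significance_tier(-0.1), "0, 1")
})

test_that("grid search is deterministic and matches the per-combination path", {
  dat <- small_dataset(seed = 9, n_years = 8)
  g <- grid_spec()
  fit1 <- grid_search(dat$series, dat$mortality, g)
  fit2 <- grid_search(dat$series, dat$mortality, g)
  expect_identical(fit1$table, fit2$table)
  expect_identical(fit1[c("tth", "lag", "alpha", "p0", "r2")],
                   fit2[c("tth", "lag", "alpha", "p0", "r2")])
  # the cached-cumsum fast path must agree with the direct per-event path
  rows <- fit1$table[!is.na(fit1$table$r2), ]
  pick <- rows[sample.int(nrow(rows), 5), ]
  for (i in seq_len(nrow(pick))) {
    et <- event_table(dat$series, dat$mortality, pick$tth[i], pick$lag[i])
    ref <- fit_event_regression(et$magnitude, et$mean_rate)
    expect_equal(ref$alpha, pick$alpha[i], tolerance = 1e-10)
    expect_equal(ref$r2, pick$r2[i], tolerance = 1e-10)
  }
  # selected combination is the table's R2 maximum under the tie-break order
  best <- rows[order(-rows$r2, rows$lag, -rows$tth), ][1, ]
  expect_equal(fit1$tth, best$tth)
  expect_equal(fit1$lag, best$lag)
})

test_that("grid search errors when no combination has enough events", {
  cold <- make_series(rep(15, 400))
  mort <- make_mortality(rpois(400, 10))
  expect_error(grid_search(cold, mort), "no .*combination")
})
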