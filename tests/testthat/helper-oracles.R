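# Independent oracles used to cross-check the implementation.

# Psychrometric wet-bulb oracle: solve the psychrometric equation
#   e = es(Tw) - gamma * (Ta - Tw)
# for Tw, with the Magnus saturation curve (kPa) and the standard
# psychrometer constant at sea level. Independent of Stull's arctangent fit.
oracle_wet_bulb <- function(ta, rh, gamma = 0.0667) {
  es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  e <- rh / 100 * es(ta)
  stats::uniroot(function(tw) es(tw) - gamma * (ta - tw) - e,
                 lower = -60, upper = ta + 1e-6, tol = 1e-8)$root
}

# Brute-force heatwave run enumerator: test every (start, length) pair for
# being a maximal run of strict exceedance. Independent of the rle-based path.
oracle_extract_events <- function(x, tth, min_run = 3) {
  n <- length(x)
  ex <- function(i) !is.na(x[i]) && x[i] > tth
  out <- list()
  for (s in seq_len(n)) {
    for (d in seq_len(n - s + 1L)) {
      if (all(vapply(s:(s + d - 1L), ex, logical(1))) &&
          (s == 1L || !ex(s - 1L)) &&
          (s + d > n || !ex(s + d)) &&
          d >= min_run) {
        out[[length(out) + 1L]] <- c(start = s, duration = d)
      }
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(start = integer(0), duration = integer(0)))
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, "start"]),
                 duration = as.integer(m[, "duration"]))
}

# Closed-form OLS via the normal equations, independent of stats::lm.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / sst
  fstat <- r2 / (1 - r2) * (n - 2)
  list(slope = slope, intercept = intercept, r2 = r2,
       p_value = stats::pf(fstat, 1, n - 2, lower.tail = FALSE))
}

# Small aligned synthetic dataset for fast pipeline-level tests.
small_dataset <- function(seed = 7, n_years = 12) {
  cfg <- synthetic_config(n_years = n_years, seed = seed)
  ser <- gen_indicator_series(cfg)
  list(config = cfg, series = ser, mortality = gen_mortality(ser, cfg))
}
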