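test_that("Stull wet-bulb matches an independent psychrometric oracle", {
  # the arctangent fit should track the psychrometric equation closely over
  # ordinary warm conditions
  for (case in list(c(20, 50), c(25, 70), c(30, 40), c(35, 60), c(30, 100))) {
    expect_equal(stull_wet_bulb(case[1], case[2]),
                 oracle_wet_bulb(case[1], case[2]),
                 tolerance = 0.3, ignore_attr = TRUE)
  }
  # frozen spot value, evaluated by hand from the formula
  expect_equal(stull_wet_bulb(20, 50), 13.699, tolerance = 1e-3)
})

test_that("Stull wet-bulb limiting behaviour and hand-computed anchor", {
  # at Ta = 0 and vanishing humidity the formula collapses to
  # atan(1.67633) - 4.686035
  expect_equal(stull_wet_bulb(0, 1e-9), atan(1.67633) - 4.686035,
               tolerance = 1e-6)
  # saturated air: wet-bulb equals dry-bulb up to formula error
  expect_lt(abs(stull_wet_bulb(30, 100) - 30), 1)
})

test_that("wet-bulb never exceeds dry-bulb beyond formula error", {
  grid <- expand.grid(ta = seq(0, 40, by = 2.5), rh = seq(5, 100, by = 5))
  tw <- stull_wet_bulb(grid$ta, grid$rh)
  expect_true(all(tw <= grid$ta + 1))
})

test_that("Stull wet-bulb rejects invalid input", {
  expect_error(stull_wet_bulb(20, 0), "rh")
  expect_error(stull_wet_bulb(20, -5), "rh")
  expect_error(stull_wet_bulb(NA, 50), "finite")
  expect_error(stull_wet_bulb(Inf, 50), "finite")
})

test_that("empirical WBGT polynomial evaluates exactly and reproducibly", {
  expect_identical(kma_wbgt(0, 0), -0.2442)
  expect_equal(kma_wbgt(25, 25), 25.3518, tolerance = 1e-12)
  expect_equal(kma_wbgt(10, 30), 19.5702, tolerance = 1e-12)
  # bitwise stability and vectorisation
  expect_identical(kma_wbgt(17.3, 29.1), kma_wbgt(17.3, 29.1))
  expect_identical(kma_wbgt(c(0, 25), c(0, 25)),
                   c(kma_wbgt(0, 0), kma_wbgt(25, 25)))
  expect_error(kma_wbgt(NA, 10), "finite")
})

test_that("reference WBGT is the 0.7/0.2/0.1 weighted average", {
  for (t in c(-5, 0, 17.2, 30)) expect_equal(reference_wbgt(t, t, t), t)
  expect_equal(reference_wbgt(30, 40, 35), 32.5)
  # recover the wet-bulb weight by least squares on random triples
  set.seed(11)
  tw <- runif(50, 10, 35); tg <- runif(50, 15, 50); ta <- runif(50, 10, 40)
  w <- reference_wbgt(tw, tg, ta)
  cf <- coef(lm(w ~ tw + tg + ta))
  expect_equal(unname(cf["tw"]), 0.7, tolerance = 1e-10)
  expect_equal(unname(cf["tg"]), 0.2, tolerance = 1e-10)
  expect_error(reference_wbgt(1, 2, NaN), "finite")
})

test_that("PMV scale factor follows 0.303 exp(-0.036 M) + 0.0275", {
  expect_equal(pmv_scale_factor(0), 0.3305, tolerance = 1e-12)
  # strictly decreasing with infimum 0.0275
  m <- seq(0, 400, by = 10)
  expect_true(all(diff(pmv_scale_factor(m)) < 0))
  expect_gt(min(pmv_scale_factor(m)), 0.0275)
  expect_equal(pmv_scale_factor(2000), 0.0275, tolerance = 1e-10)
  expect_error(pmv_scale_factor(-1), ">= 0")
})

test_that("PMV matches published reference computations at comfort points", {
  # seated office conditions (1.2 met = 69.84 W/m2, 0.5 clo, still air);
  # expected PMV from the ISO 7730 reference tables
  still <- reference_person(metabolic_rate = 69.84, clo = 0.5,
                            walking_speed = 0)
  expect_equal(compute_pmv(22, 60, 0.1, 22, person = still), -0.75,
               tolerance = 0.1)
  expect_equal(compute_pmv(27, 60, 0.1, 27, person = still), 0.77,
               tolerance = 0.1)
  expect_equal(compute_pmv(27, 60, 0.3, 27, person = still), 0.44,
               tolerance = 0.1)
})

test_that("PMV is monotone in air and radiant temperature and deterministic", {
  ta <- seq(20, 40, by = 1)
  pmv <- compute_pmv(ta, 50, 1.5)
  expect_true(all(diff(pmv) > 0))
  tmrt <- seq(20, 60, by = 2)
  pmv_r <- compute_pmv(30, 50, 1.5, tmrt)
  expect_true(all(diff(pmv_r) > 0))
  expect_identical(compute_pmv(31.7, 63, 2.2), compute_pmv(31.7, 63, 2.2))
})

test_that("PMV-to-PT heat-branch translation is exact", {
  expect_identical(pt_from_pmv(0), 16.83)
  expect_equal(pt_from_pmv(1), 23.01, tolerance = 1e-12)
  # slope by finite differencing
  expect_equal((pt_from_pmv(2 + 1e-6) - pt_from_pmv(2)) / 1e-6, 6.18,
               tolerance = 1e-6)
  pmv <- seq(0, 4, by = 0.25)
  expect_true(all(diff(pt_from_pmv(pmv)) > 0))
  expect_error(pt_from_pmv(-0.5), "heat branch")
})

test_that("mean radiant temperature estimator honours its fallbacks", {
  noon <- as.POSIXct("2010-07-15 12:00:00", tz = "UTC")
  midnight <- as.POSIXct("2010-07-15 00:00:00", tz = "UTC")
  # night and full overcast fall back to Ta
  expect_equal(estimate_mrt(25, 0, 37.5, midnight), 25)
  expect_equal(estimate_mrt(30, 1, 37.5, noon), 30)
  # clear summer noon gains shortwave heat
  expect_gt(estimate_mrt(30, 0, 37.5, noon), 30)
  # missing cloud information falls back with a warning
  expect_warning(out <- estimate_mrt(30, NA, 37.5, noon), "cloud")
  expect_equal(out, 30)
})

test_that("daily maxima respect the completeness threshold and input order", {
  base <- as.POSIXct("2012-08-01 00:00:00", tz = "UTC")
  ts <- base + 3600 * (0:23)
  vals <- c(rep(25, 15), 31.2, rep(24, 8))
  dm <- daily_max(ts, vals)
  expect_s3_class(dm, "daily_series")
  expect_equal(dm$value, 31.2)
  # 10 valid hours < 18 required: the day is missing
  sparse <- daily_max(ts, replace(vals, 1:14, NA))
  expect_true(is.na(sparse$value))
  # shuffled two-day input gives the same result as sorted input
  ts2 <- c(ts, ts + 86400)
  vals2 <- c(vals, vals + 2)
  ord <- sample(seq_along(ts2))
  expect_equal(daily_max(ts2[ord], vals2[ord])$value, daily_max(ts2, vals2)$value)
  expect_error(daily_max(numeric(0), numeric(0)), "empty")
})

test_that("hourly chain produces PT daily maxima in the afternoon", {
  cfg <- synthetic_config(seed = 3)
  met <- gen_hourly_met(cfg, n_days = 5)
  met_summer <- gen_hourly_met(cfg, n_days = 3)
  pmv <- compute_pmv(met$ta, met$rh, met$wind)
  # heat branch only where PMV >= 0; daily max of PT is defined from those
  pt <- ifelse(pmv >= 0, 6.18 * pmv + 16.83, NA)
  expect_true(all(is.finite(pmv)))
  # diurnal Ta peak is mid-afternoon by construction; PMV peaks with it
  hour_of_max <- (which.max(pmv[1:24]) - 1)
  expect_true(hour_of_max %in% 12:18)
})
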