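#' Reference person for the perceived-temperature heat balance
#'
#' The standard reference person used for perceived temperature: a 35-year-old
#' male, 1.75 m, 75 kg, walking at 4 km/h on flat ground in summer clothing
#' (0.5 clo). Walking at 4 km/h corresponds to a metabolic rate of about
#' 135 W m^-2 with no external mechanical work.
#'
#' @param age Age in years (informational only).
#' @param height Height in m.
#' @param weight Weight in kg.
#' @param metabolic_rate Metabolic rate M in W m^-2; must be > 0.
#' @param external_work External mechanical work W in W m^-2; must be >= 0.
#' @param clo Clothing insulation in clo (1 clo = 0.155 m^2 K W^-1); >= 0.
#' @param walking_speed Walking speed in m/s (4 km/h = 1.11 m/s).
#' @return A list of class `reference_person`.
#' @export
reference_person <- function(age = 35, height = 1.75, weight = 75,
                             metabolic_rate = 135, external_work = 0,
                             clo = 0.5, walking_speed = 1.11) {
  stopifnot(metabolic_rate > 0, external_work >= 0, clo >= 0, walking_speed >= 0)
  structure(
    list(age = age, height = height, weight = weight,
         metabolic_rate = metabolic_rate, external_work = external_work,
         clo = clo, walking_speed = walking_speed),
    class = "reference_person"
  )
}

#' @export
print.reference_person <- function(x, ...) {
  cat(sprintf(
    "<reference_person> %g y, %.2f m, %g kg; M = %g W/m^2, W = %g W/m^2, %g clo, walking %g m/s\n",
    x$age, x$height, x$weight, x$metabolic_rate, x$external_work, x$clo,
    x$walking_speed))
  invisible(x)
}

#' PMV scale factor
#'
#' Dimensionless factor that rescales the thermal load on the body to the
#' predicted-mean-vote comfort scale: 0.303 exp(-0.036 M) + 0.0275. Strictly
#' decreasing in the metabolic rate with limit 0.0275.
#'
#' @param m Metabolic rate in W m^-2; must be >= 0.
#' @return The scale factor (dimensionless).
#' @export
pmv_scale_factor <- function(m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
    stop("`m` must be finite and >= 0", call. = FALSE)
  0.303 * exp(-0.036 * m) + 0.0275
}

# Saturation vapour pressure over water (Pa), Magnus form used by the
# ISO 7730 reference computation.
vapour_pressure <- function(ta, rh) {
  rh * 10 * exp(16.6536 - 4030.183 / (ta + 235))
}

#' Predicted mean vote from a steady-state heat balance
#'
#' Computes the predicted mean vote (PMV) by the Fanger steady-state heat
#' balance: convective, radiative and evaporative skin losses plus respiratory
#' losses are subtracted from the net metabolic heat production to give the
#' thermal load `l_th`, which is rescaled by [pmv_scale_factor()]. The
#' clothing-surface temperature is solved by damped fixed-point iteration
#' (tolerance 1e-4 degC, at most 150 iterations).
#'
#' The relative air speed seen by the walking reference person is the
#' magnitude of the vector sum of the wind and the walking speed, taken as
#' orthogonal: sqrt(wind^2 + walking^2).
#'
#' @param ta Air temperature in degC.
#' @param rh Relative humidity in percent.
#' @param wind Wind speed in m/s (>= 0).
#' @param tmrt Mean radiant temperature in degC; defaults to `ta` when not
#'   supplied (see [estimate_mrt()] for a radiation-based estimate).
#' @param person A [reference_person()].
#' @return PMV (dimensionless), vectorised over the meteorological inputs.
#' @examples
#' compute_pmv(ta = 30, rh = 60, wind = 1)
#' @export
compute_pmv <- function(ta, rh, wind, tmrt = NULL, person = reference_person()) {
  if (is.null(tmrt)) tmrt <- ta
  n <- max(length(ta), length(rh), length(wind), length(tmrt))
  ta <- rep_len(ta, n); rh <- rep_len(rh, n)
  wind <- rep_len(wind, n); tmrt <- rep_len(tmrt, n)
  if (any(!is.finite(ta)) || any(!is.finite(rh)) || any(!is.finite(wind)) ||
      any(!is.finite(tmrt)))
    stop("meteorological inputs must be finite", call. = FALSE)
  if (any(rh < 0 | rh > 100)) stop("`rh` must lie in [0, 100]", call. = FALSE)
  if (any(wind < 0)) stop("`wind` must be >= 0", call. = FALSE)
  vapply(seq_len(n), function(i) {
    pmv_scale_factor(person$metabolic_rate) *
      thermal_load(ta[i], rh[i], wind[i], tmrt[i], person)
  }, numeric(1))
}

# Thermal load L_th (W m^-2) on the body: net metabolic heat minus skin
# (convective, radiative, evaporative) and respiratory losses, under the
# steady-state assumption (no heat storage in skin or core).
thermal_load <- function(ta, rh, wind, tmrt, person) {
  m <- person$metabolic_rate
  w <- person$external_work
  mw <- m - w
  icl <- 0.155 * person$clo            # m^2 K / W
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  vel <- sqrt(wind^2 + person$walking_speed^2)
  pa <- vapour_pressure(ta, rh)        # Pa

  taa <- ta + 273
  tra <- tmrt + 273
  hcf <- 12.1 * sqrt(vel)
  # clothing surface temperature by damped fixed-point iteration
  tcla <- taa + (35.5 - ta) / (3.5 * icl + 0.1)
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * mw + p2 * (tra / 100)^4
  xn <- tcla / 100
  xf <- tcla / 50
  eps <- 1e-6                          # on xn = tcl/100, i.e. 1e-4 degC
  hc <- hcf
  it <- 0L
  while (abs(xn - xf) > eps) {
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa)^0.25
    hc <- max(hcf, hcn)
    xn <- (p5 + p4 * hc - p2 * xf^4) / (100 + p3 * hc)
    it <- it + 1L
    if (it > 150L)
      stop(sprintf(
        "clothing-surface temperature iteration did not converge (150 iterations, residual %.3g degC)",
        abs(xn - xf) * 100), call. = FALSE)
  }
  tcl <- 100 * xn - 273

  e_skin <- 3.05e-3 * (5733 - 6.99 * mw - pa) +       # diffusion
    if (mw > 58.15) 0.42 * (mw - 58.15) else 0         # sweating
  e_res <- 1.7e-5 * m * (5867 - pa)                    # latent respiration
  c_res <- 0.0014 * m * (34 - ta)                      # dry respiration
  r_skin <- 3.96 * fcl * (xn^4 - (tra / 100)^4)
  c_skin <- fcl * hc * (tcl - ta)

  mw - e_skin - e_res - c_res - r_skin - c_skin
}

#' Perceived temperature from PMV (heat branch)
#'
#' Linear translation of the predicted mean vote to perceived temperature on
#' the heat-stress branch: PT = 6.18 PMV + 16.83, valid for PMV >= 0. The
#' boundary PMV = 0 is accepted so the translation is continuous there;
#' negative PMV (cold stress) uses different formulas and is out of scope.
#'
#' @param pmv Predicted mean vote, >= 0.
#' @return Perceived temperature in degC.
#' @examples
#' pt_from_pmv(1)
#' @export
pt_from_pmv <- function(pmv) {
  if (!is.numeric(pmv) || any(!is.finite(pmv)))
    stop("`pmv` must be finite", call. = FALSE)
  if (any(pmv < 0))
    stop("perceived temperature is only defined here on the heat branch (PMV >= 0)",
         call. = FALSE)
  6.18 * pmv + 16.83
}

#' Simple mean radiant temperature estimate
#'
#' A deliberately simple clear-sky estimator used when mean radiant
#' temperature is not observed: during daytime the shortwave gain raises Tmrt
#' above the air temperature in proportion to the sine of the solar elevation,
#' attenuated linearly by cloud cover; at night or under full overcast
#' Tmrt = Ta. Timestamps are interpreted as local solar time. When cloud
#' information is missing the estimator falls back to Tmrt = Ta with a
#' warning. The downstream mortality model is driven by daily maxima and is
#' insensitive to the details of this scheme; a measured or modelled Tmrt can
#' always be supplied directly.
#'
#' @param ta Air temperature in degC.
#' @param cloud Cloud cover fraction in \[0, 1\] (NA allowed).
#' @param lat Latitude in degrees.
#' @param time POSIXct local solar time of the observation.
#' @param dt_clear Maximum clear-sky Tmrt elevation above Ta at solar zenith,
#'   in K (default 15).
#' @return Estimated mean radiant temperature in degC.
#' @export
estimate_mrt <- function(ta, cloud, lat, time, dt_clear = 15) {
  n <- max(length(ta), length(cloud), length(time))
  ta <- rep_len(ta, n); cloud <- rep_len(cloud, n)
  time <- rep(time, length.out = n)
  if (any(is.na(cloud))) {
    warning("missing cloud amount: falling back to Tmrt = Ta for those hours")
  }
  lt <- as.POSIXlt(time)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  hang <- (hour - 12) * 15 * pi / 180
  latr <- lat * pi / 180
  sin_elev <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(hang)
  gain <- dt_clear * pmax(sin_elev, 0) * (1 - cloud)
  gain[is.na(cloud)] <- 0
  ta + gain
}
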