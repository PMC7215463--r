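#' Stull's wet-bulb temperature approximation
#'
#' Estimates the natural wet-bulb temperature from air temperature and
#' relative humidity using Stull's single-equation arctangent fit (arctangents
#' in radians). The fit was calibrated for ordinary surface conditions at
#' standard pressure; values far outside roughly -20..50 degC or very low
#' humidity carry larger formula error, which is not enforced here.
#'
#' @param ta Air temperature in degC.
#' @param rh Relative humidity in percent, in (0, 100].
#' @return Wet-bulb temperature in degC.
#' @examples
#' stull_wet_bulb(20, 50)
#' @export
stull_wet_bulb <- function(ta, rh) {
  if (length(ta) != length(rh)) {
    if (length(ta) == 1L) ta <- rep(ta, length(rh))
    else if (length(rh) == 1L) rh <- rep(rh, length(ta))
    else stop("`ta` and `rh` must have equal (or recyclable) lengths", call. = FALSE)
  }
  if (!is.numeric(ta) || !is.numeric(rh) || any(!is.finite(ta)) || any(!is.finite(rh)))
    stop("`ta` and `rh` must be finite numbers", call. = FALSE)
  if (any(rh <= 0) || any(rh > 100))
    stop("`rh` must lie in (0, 100]", call. = FALSE)
  ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) - atan(rh - 1.67633) +
    0.00391838 * rh^(3 / 2) * atan(0.023101 * rh) -
    4.686035
}

#' Empirical Korean WBGT polynomial
#'
#' Wet-bulb globe temperature estimated from the natural wet-bulb and air
#' temperatures by the two-variable quadratic in operational use in South
#' Korea, avoiding the need for black-globe observations.
#'
#' @param tw Natural wet-bulb temperature in degC.
#' @param ta Air temperature in degC.
#' @return WBGT in degC.
#' @examples
#' kma_wbgt(25, 25)
#' @export
kma_wbgt <- function(tw, ta) {
  if (!is.numeric(tw) || !is.numeric(ta) || any(!is.finite(tw)) || any(!is.finite(ta)))
    stop("`tw` and `ta` must be finite numbers", call. = FALSE)
  -0.2442 + 0.55399 * tw + 0.45535 * ta - 0.0022 * tw^2 + 0.00278 * tw * ta
}

#' Reference (Yaglou) WBGT weighted average
#'
#' The defining 0.7/0.2/0.1 weighted average of natural wet-bulb, black-globe
#' and air temperature. Provided for cross-checks against the empirical
#' polynomial; the pipeline itself uses [kma_wbgt()] because black-globe
#' temperature is rarely observed at weather stations.
#'
#' @param tw Natural wet-bulb temperature in degC.
#' @param tg Black-globe temperature in degC.
#' @param ta Air temperature in degC.
#' @return WBGT in degC.
#' @export
reference_wbgt <- function(tw, tg, ta) {
  if (!is.numeric(tw) || !is.numeric(tg) || !is.numeric(ta) ||
      any(!is.finite(tw)) || any(!is.finite(tg)) || any(!is.finite(ta)))
    stop("all inputs must be finite numbers", call. = FALSE)
  0.7 * tw + 0.2 * tg + 0.1 * ta
}
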