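#' Coefficients of the analytic clear-sky UVI model
#'
#' The clear-sky ultraviolet index is modelled as a power law in the cosine of
#' the solar zenith angle and the total ozone column (TOC),
#' `uvi0 * mu0^mu0_exp * (toc/toc_ref)^toc_exp`. The default coefficients are
#' the widely used analytical fit for cloud- and aerosol-free conditions at
#' sea level; they are configuration values, not constants baked into the
#' model functions.
#'
#' @param uvi0 Leading coefficient: the UVI at overhead sun and reference TOC.
#' @param mu0_exp Exponent of the cosine of the solar zenith angle.
#' @param toc_exp Exponent of the ozone ratio (negative: more ozone, less UV).
#' @param toc_ref Reference total ozone column in Dobson units.
#'
#' @return A named list of class `clearsky_coef`.
#' @export
clearsky_coef <- function(uvi0 = 12.50, mu0_exp = 2.42, toc_exp = -1.23,
                          toc_ref = 300) {
  stopifnot(uvi0 > 0, mu0_exp > 0, toc_ref > 0)
  structure(list(uvi0 = uvi0, mu0_exp = mu0_exp, toc_exp = toc_exp,
                 toc_ref = toc_ref),
            class = "clearsky_coef")
}

#' Clear-sky UVI from solar zenith angle and total ozone column
#'
#' Evaluates the analytic clear-sky power law at sea level. Returns 0 whenever
#' the sun is at or below the horizon (SZA >= 90 degrees); the power of
#' `mu0` drives the index continuously to zero as the SZA approaches 90.
#'
#' @param sza Solar zenith angle(s) in degrees, in \[0, 180\].
#' @param toc Total ozone column(s) in Dobson units, > 0.
#' @param coef A [clearsky_coef()] set.
#'
#' @return Numeric vector of UVI values (>= 0).
#' @examples
#' clearsky_uvi(0, 300)    # 12.5 at overhead sun, reference ozone
#' clearsky_uvi(60, 300)
#' @export
clearsky_uvi <- function(sza, toc, coef = clearsky_coef()) {
  if (any(!is.finite(toc)) || any(toc <= 0)) {
    abort("`toc` must be positive (Dobson units).")
  }
  if (any(!is.finite(sza)) || any(sza < 0 | sza > 180)) {
    abort("`sza` must lie in [0, 180] degrees.")
  }
  mu0 <- cos(pmin(sza, 90) * pi / 180)
  uvi <- coef$uvi0 * mu0^coef$mu0_exp * (toc / coef$toc_ref)^coef$toc_exp
  ifelse(sza >= 90, 0, uvi)
}

#' Adjust a UVI value for altitude
#'
#' Applies a linear altitude gradient, `uvi * (1 + rate * altitude_km)`. The
#' default 6 % per km is the conventional mid-range UV altitude effect;
#' realistic values span roughly 5-8 % per km.
#'
#' @param uvi UVI value(s), >= 0.
#' @param altitude_km Altitude(s) above sea level in kilometres, >= 0.
#' @param rate Fractional increase per kilometre, in \[0, 0.25\].
#'
#' @return Adjusted UVI values.
#' @examples
#' altitude_adjust(10, 2.36)   # Karthala summit
#' @export
altitude_adjust <- function(uvi, altitude_km, rate = 0.06) {
  if (any(!is.finite(altitude_km)) || any(altitude_km < 0)) {
    abort("`altitude_km` must be non-negative.")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 0.25) {
    abort("`rate` must be a single value in [0, 0.25] (fraction per km).")
  }
  uvi * (1 + rate * altitude_km)
}

#' Daily clear-sky UVI reference profile
#'
#' Evaluates the clear-sky model at every minute of a station-local calendar
#' day, giving the bell-shaped reference profile used by the bell-shape
#' clear-sky filter and by the synthetic generator. The profile is zero
#' outside daylight and peaks at local solar noon.
#'
#' @param station A [uv_station()].
#' @param date Station-local calendar date.
#' @param toc Total ozone column for the day, Dobson units.
#' @param altitude_km Altitude at which to evaluate; defaults to the station
#'   altitude.
#' @param rate Altitude gradient passed to [altitude_adjust()].
#' @param sky_factor Constant multiplicative factor absorbing aerosol and
#'   surface-albedo effects (default 1).
#' @param coef A [clearsky_coef()] set.
#'
#' @return A tibble with 1440 rows: `timestamp` (UTC), `sza`, `uvi_cs`, and
#'   attributes `toc` and `altitude_km`.
#' @export
daily_clearsky_profile <- function(station, date, toc,
                                   altitude_km = station$altitude_km,
                                   rate = 0.06, sky_factor = 1,
                                   coef = clearsky_coef()) {
  assert_station(station)
  if (!is.numeric(toc) || length(toc) != 1 || !is.finite(toc) || toc <= 0) {
    abort("`toc` must be a single positive value (Dobson units).")
  }
  if (!is.numeric(sky_factor) || sky_factor < 0) {
    abort("`sky_factor` must be non-negative.")
  }
  minutes <- day_minute_grid(station, date)
  pos <- solar_position(station, minutes)
  uvi <- clearsky_uvi(pos$sza, toc, coef = coef)
  uvi <- altitude_adjust(uvi, altitude_km, rate = rate) * sky_factor
  out <- tibble(timestamp = minutes, sza = pos$sza, uvi_cs = uvi)
  attr(out, "toc") <- toc
  attr(out, "altitude_km") <- altitude_km
  out
}

#' Apply a cloud modification factor
#'
#' Multiplies clear-sky UVI by a cloud modification factor (CMF): values
#' below 1 represent attenuation (heavy overcast can remove 80 % of the
#' clear-sky index), values above 1 represent broken-cloud enhancement
#' (typically up to about 20 %).
#'
#' @param uvi_cs Clear-sky UVI value(s).
#' @param cmf Cloud modification factor(s), >= 0.
#'
#' @return All-sky UVI values.
#' @export
apply_cloud_modification <- function(uvi_cs, cmf) {
  if (any(!is.finite(cmf)) || any(cmf < 0)) {
    abort("`cmf` must be non-negative.")
  }
  uvi_cs * cmf
}
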