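#' Solar position from a low-precision ephemeris
#'
#' Computes the solar zenith angle (SZA) and its cosine for a station and a
#' vector of UTC instants using the NOAA/Spencer Fourier-series ephemeris
#' (fractional-year expansion of solar declination and the equation of time).
#' Accuracy is a few hundredths of a degree over 1950-2100, far better than
#' the half-degree needed for a 45 degree clear-sky gate and the power-law
#' clear-sky model. Atmospheric refraction is ignored; it is irrelevant at
#' the zenith angles where UV matters.
#'
#' @param station A [uv_station()].
#' @param time A `POSIXct` vector (interpreted in UTC) within 1950-2100.
#'
#' @return A tibble with columns `timestamp`, `sza` (degrees, in \[0, 180\])
#'   and `mu0` (cosine of the SZA).
#' @examples
#' solar_position(moroni_station(),
#'                as.POSIXct("2020-01-15 09:00:00", tz = "UTC"))
#' @export
solar_position <- function(station, time) {
  assert_station(station)
  time <- as_utc(time)
  yr <- lubridate::year(time)
  if (length(time) == 0) abort("`time` must contain at least one instant.")
  if (any(is.na(time))) abort("`time` contains missing values.")
  if (any(yr < 1950 | yr > 2100)) {
    abort("timestamps must fall within 1950-2100 (ephemeris validity window).")
  }
  eph <- ephemeris_terms(time)
  hour_frac <- lubridate::hour(time) + lubridate::minute(time) / 60 +
    lubridate::second(time) / 3600
  ## true solar time in minutes, then hour angle in degrees
  tst <- (hour_frac * 60 + eph$eqtime_min + 4 * station$longitude) %% 1440
  ha <- tst / 4 - 180
  lat <- station$latitude * pi / 180
  mu0 <- sin(lat) * sin(eph$decl_rad) +
    cos(lat) * cos(eph$decl_rad) * cos(ha * pi / 180)
  mu0 <- pmin(pmax(mu0, -1), 1)
  tibble(timestamp = time, sza = acos(mu0) * 180 / pi, mu0 = mu0)
}

#' Solar zenith angle
#'
#' Vectorised shorthand for the `sza` column of [solar_position()].
#'
#' @inheritParams solar_position
#' @return Numeric vector of zenith angles in degrees.
#' @export
solar_zenith_angle <- function(station, time) {
  solar_position(station, time)$sza
}

#' Local solar noon
#'
#' The UTC instant of minimum solar zenith angle on a given calendar date,
#' from the equation of time: noon occurs at `12:00 UTC - 4 * longitude
#' minutes - equation of time`. Accurate to well under a minute against a
#' brute-force minute scan of the SZA.
#'
#' @param station A [uv_station()].
#' @param date A `Date` (or something coercible by [lubridate::as_date()]).
#'   The date is interpreted as the station-local calendar date.
#'
#' @return A `POSIXct` UTC instant, one per input date.
#' @examples
#' local_solar_noon(moroni_station(), as.Date("2020-01-12"))
#' @export
local_solar_noon <- function(station, date) {
  assert_station(station)
  date <- lubridate::as_date(date)
  if (any(is.na(date))) abort("`date` contains missing values.")
  ## first guess: mean solar noon for the meridian; one refinement of the
  ## equation of time at the guessed instant is ample (EoT drifts < 0.5
  ## min/day)
  guess <- lubridate::as_datetime(date, tz = "UTC") +
    (12 - station$longitude / 15) * 3600
  for (i in 1:2) {
    eot <- ephemeris_terms(guess)$eqtime_min
    guess <- lubridate::as_datetime(date, tz = "UTC") +
      (720 - 4 * station$longitude - eot) * 60
  }
  guess
}

## Spencer's Fourier expansion of declination (radians) and equation of time
## (minutes) on the fractional year.
ephemeris_terms <- function(time) {
  time <- as_utc(time)
  doy <- lubridate::yday(time)
  hour_frac <- lubridate::hour(time) + lubridate::minute(time) / 60 +
    lubridate::second(time) / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour_frac - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime_min = eqtime, decl_rad = decl)
}

as_utc <- function(time) {
  if (!inherits(time, "POSIXct")) {
    abort("timestamps must be POSIXct (UTC).")
  }
  lubridate::with_tz(time, "UTC")
}

## minute grid spanning one station-local calendar day, returned as UTC
day_minute_grid <- function(station, date) {
  date <- lubridate::as_date(date)
  start <- lubridate::as_datetime(date, tz = "UTC") - station$utc_offset * 3600
  start + seq(0, by = 60, length.out = 1440)
}
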