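#' Describe a ground measurement station
#'
#' Bundles the geographic metadata every solar-geometry and clear-sky
#' computation needs: latitude, longitude, altitude and the civil UTC offset.
#' All timestamps in the package are handled in UTC; the offset is only used
#' when grouping by station-local calendar day or minute-of-day.
#'
#' @param latitude Degrees north, in \[-90, 90\].
#' @param longitude Degrees east, in \[-180, 180\].
#' @param altitude_km Altitude above sea level in kilometres, >= 0.
#' @param utc_offset Civil time offset from UTC in hours.
#' @param name Optional station label.
#'
#' @return An object of class `uv_station` (a named list).
#' @examples
#' uv_station(-11.708, 43.247, altitude_km = 0.012, utc_offset = 3, name = "Moroni")
#' @export
uv_station <- function(latitude, longitude, altitude_km = 0, utc_offset = 0,
                       name = "station") {
  if (!is.numeric(latitude) || length(latitude) != 1 || is.na(latitude) ||
      latitude < -90 || latitude > 90) {
    abort("`latitude` must be a single value in [-90, 90].")
  }
  if (!is.numeric(longitude) || length(longitude) != 1 || is.na(longitude) ||
      longitude < -180 || longitude > 180) {
    abort("`longitude` must be a single value in [-180, 180].")
  }
  if (!is.numeric(altitude_km) || length(altitude_km) != 1 || is.na(altitude_km) ||
      altitude_km < 0) {
    abort("`altitude_km` must be a single non-negative value.")
  }
  if (!is.numeric(utc_offset) || length(utc_offset) != 1 || is.na(utc_offset)) {
    abort("`utc_offset` must be a single numeric value (hours).")
  }
  structure(
    list(latitude = latitude, longitude = longitude,
         altitude_km = altitude_km, utc_offset = utc_offset,
         name = as.character(name)),
    class = "uv_station"
  )
}

#' The Moroni (Comoros) station
#'
#' Convenience constructor for the tropical island station the package's
#' examples and synthetic generator emulate: 11.708 degrees S, 43.247 degrees E,
#' 12 m above sea level, civil time UTC+3.
#'
#' @return A [uv_station()] object.
#' @export
moroni_station <- function() {
  uv_station(-11.708, 43.247, altitude_km = 0.012, utc_offset = 3,
             name = "Moroni")
}

#' @export
print.uv_station <- function(x, ...) {
  cat(sprintf("<uv_station> %s: %.3f deg lat, %.3f deg lon, %.3f km asl, UTC%+g\n",
              x$name, x$latitude, x$longitude, x$altitude_km, x$utc_offset))
  invisible(x)
}

is_uv_station <- function(x) inherits(x, "uv_station")

assert_station <- function(station) {
  if (!is_uv_station(station)) {
    abort("`station` must be a `uv_station` object; see `uv_station()`.")
  }
  invisible(station)
}

## station-local clock time (POSIXct still carries tz UTC; only the clock
## reading is shifted). Used for local-day and minute-of-day grouping.
local_time <- function(timestamp, station) {
  timestamp + station$utc_offset * 3600
}

local_date <- function(timestamp, station) {
  lubridate::as_date(local_time(timestamp, station))
}

local_minute_of_day <- function(timestamp, station) {
  lt <- local_time(timestamp, station)
  lubridate::hour(lt) * 60L + lubridate::minute(lt)
}
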