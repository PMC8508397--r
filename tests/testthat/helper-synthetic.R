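utc <- function(x) as.POSIXct(x, tz = "UTC")

equator_station <- function() uv_station(0, 0, altitude_km = 0, utc_offset = 0)

## brute-force daily SZA minimum: scan all 1440 minutes of the UTC day
## containing local mean solar noon
brute_force_noon <- function(station, date) {
  approx_noon <- lubridate::as_datetime(date, tz = "UTC") +
    (12 - station$longitude / 15) * 3600
  grid <- approx_noon + seq(-720, 719) * 60
  sza <- solar_zenith_angle(station, grid)
  grid[which.min(sza)]
}

## one-day series on the station minute grid with a given uvi vector
grid_series <- function(station, date, uvi, source = "TEST") {
  ts <- erythemal:::day_minute_grid(station, date)
  tibble::tibble(timestamp = ts, uvi = uvi, source = source,
                 flag = NA_character_)
}

## quiet-sky config used across tests: no sensor noise, no enhancement
quiet_config <- function(seed = 101, ...) {
  synthetic_config(seed = seed, sensor_noise_sd = 0, p_enhance = 0, ...)
}
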