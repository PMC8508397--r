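#' Extract one value per day at local solar noon (or at overpass time)
#'
#' For each station-local day in the series, picks the sample nearest to the
#' target instant -- local solar noon, optionally shifted by an overpass
#' offset -- provided it lies within `tol_min` minutes; days without a close
#' enough sample get NA. Polar-orbiter overpasses at this longitude trail
#' local solar noon by about an hour, hence the default offset of
#' [extract_overpass()].
#'
#' @param series A UVI series tibble.
#' @param station A [uv_station()].
#' @param offset_min Minutes after local solar noon to target (>= 0).
#' @param tol_min Matching tolerance in minutes (default 5).
#'
#' @return A tibble `day`, `target` (UTC instant aimed at), `timestamp`
#'   (sample actually used, NA when none), `uvi`.
#' @export
extract_noon <- function(series, station, offset_min = 0, tol_min = 5) {
  assert_uvi_series(series)
  assert_station(station)
  if (offset_min < 0) abort("`offset_min` must be >= 0.")
  days <- sort(unique(local_date(series$timestamp, station)))
  target <- local_solar_noon(station, days) + offset_min * 60
  idx <- nearest_match(target, series$timestamp, tol_min * 60)
  tibble(day = days, target = target,
         timestamp = series$timestamp[idx],
         uvi = series$uvi[idx])
}

#' @rdname extract_noon
#' @export
extract_overpass <- function(series, station, offset_min = 60, tol_min = 5) {
  extract_noon(series, station, offset_min = offset_min, tol_min = tol_min)
}

#' Monthly climatology with boxplot statistics
#'
#' Summarises one value per day into per-month boxplot statistics: mean, sd,
#' median, quartiles (linear interpolation), Tukey fences at 1.5 IQR (the
#' standard equivalent of flagging points beyond about +/- 2.7 sigma for
#' normal data), whiskers at the most extreme non-outlier points, and the
#' outliers themselves.
#'
#' @param daily_values A tibble with columns `day` (Date) and `value`
#'   (NAs dropped).
#'
#' @return A tibble with one row per calendar month (1-12): `month`, `n`,
#'   `mean`, `sd`, `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   and `outliers` (list column). Months without data have `n = 0` and NA
#'   statistics.
#' @export
monthly_climatology <- function(daily_values) {
  if (!all(c("day", "value") %in% names(daily_values))) {
    abort("`daily_values` must have columns day and value.")
  }
  filled <- daily_values |>
    filter(!is.na(.data$value)) |>
    mutate(month = lubridate::month(.data$day)) |>
    group_by(.data$month) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$value), sd = sd(.data$value),
              median = median(.data$value),
              q25 = quantile(.data$value, 0.25, type = 7, names = FALSE),
              q75 = quantile(.data$value, 0.75, type = 7, names = FALSE),
              values = list(.data$value),
              .groups = "drop") |>
    mutate(
      fence_low = .data$q25 - 1.5 * (.data$q75 - .data$q25),
      fence_high = .data$q75 + 1.5 * (.data$q75 - .data$q25),
      outliers = purrr::pmap(list(.data$values, .data$fence_low, .data$fence_high),
                             function(v, lo, hi) v[v < lo | v > hi]),
      whisker_low = purrr::pmap_dbl(list(.data$values, .data$fence_low, .data$fence_high),
                                    function(v, lo, hi) min(v[v >= lo & v <= hi])),
      whisker_high = purrr::pmap_dbl(list(.data$values, .data$fence_low, .data$fence_high),
                                     function(v, lo, hi) max(v[v >= lo & v <= hi]))
    ) |>
    select("month", "n", "mean", "sd", "median", "q25", "q75",
           "whisker_low", "whisker_high", "outliers")
  tibble(month = 1:12) |>
    left_join(filled, by = "month") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Mean diurnal cycle by station-local minute of day
#'
#' Groups samples by local minute-of-day and reports mean, standard deviation
#' and the sample count per minute. The count column doubles as a data-
#' availability diagnostic: after clear-sky filtering it mirrors (inversely)
#' the diurnal cloud cycle.
#'
#' @param series A tibble with `timestamp` and a value column.
#' @param station A [uv_station()].
#' @param value Name of the value column (default `"uvi"`).
#'
#' @return A tibble `minute_of_day` (0-1439), `mean`, `sd`, `count`, with
#'   rows only for minutes that have data.
#' @export
diurnal_cycle <- function(series, station, value = "uvi") {
  assert_timestamps(series, "series")
  assert_station(station)
  if (!value %in% names(series)) {
    abort(sprintf("column `%s` not found in `series`.", value))
  }
  series |>
    transmute(minute_of_day = local_minute_of_day(.data$timestamp, station),
              v = .data[[value]]) |>
    filter(!is.na(.data$v)) |>
    group_by(.data$minute_of_day) |>
    summarise(mean = mean(.data$v), sd = sd(.data$v), count = dplyr::n(),
              .groups = "drop")
}
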