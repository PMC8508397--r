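#' Convert UVI to erythemally weighted irradiance
#'
#' By definition one UVI unit corresponds to 0.025 W m-2 of erythemally
#' weighted irradiance, i.e. irradiance = uvi / 40.
#'
#' @param uvi Non-negative UVI value(s).
#' @return Irradiance in W m-2.
#' @export
uvi_to_erythemal_irradiance <- function(uvi) {
  if (any(uvi < 0, na.rm = TRUE)) abort("`uvi` must be non-negative.")
  uvi / 40
}

#' Erythemal dose per time window
#'
#' Integrates a minute-resolution UVI series into standard erythemal doses
#' (SED; 1 SED = 100 J m-2): each window's dose is the mean erythemal
#' irradiance over the window times the window length in seconds, divided by
#' 100. Windows are aligned to station-local midnight. A constant UVI of 20
#' over one minute gives 0.30 SED.
#'
#' Gap policy: the series is regularised to a 1-minute grid per station-local
#' day; gaps up to `gap_max_min` minutes are filled by linear interpolation,
#' longer gaps contribute zero dose and mark the day as `partial`.
#'
#' @param uvi A UVI series tibble.
#' @param window Window length in seconds; must be a positive multiple of 60
#'   (default 60).
#' @param station A [uv_station()]; its UTC offset defines the local day.
#'   Defaults to a zero-offset station at the origin.
#' @param gap_max_min Longest gap (minutes) bridged by interpolation.
#'
#' @return A tibble with `window_start` (UTC), `day` (station-local date),
#'   `sed` and a logical `partial` flag per day.
#' @export
sed_per_window <- function(uvi, window = 60, station = uv_station(0, 0),
                           gap_max_min = 10) {
  assert_uvi_series(uvi)
  assert_station(station)
  if (!is.numeric(window) || length(window) != 1 || window <= 0 ||
      window %% 60 != 0) {
    abort("`window` must be a positive multiple of 60 seconds.")
  }
  w_min <- as.integer(window / 60)

  obs <- uvi |>
    filter(!is.na(.data$uvi)) |>
    transmute(timestamp = .data$timestamp, uvi = .data$uvi,
              day = local_date(.data$timestamp, station))
  if (nrow(obs) == 0) abort("UVI series has no non-missing samples.")

  per_day <- obs |>
    group_by(.data$day) |>
    group_modify(function(d, key) {
      grid <- day_minute_grid(station, key$day[[1]])
      if (nrow(d) >= 2) {
        filled <- approx(as.numeric(d$timestamp), d$uvi,
                         xout = as.numeric(grid), method = "linear",
                         rule = 1, ties = mean)$y
      } else {
        filled <- rep(d$uvi[1], 1440)
      }
      ## interpolation may only bridge short gaps: drop grid minutes further
      ## than gap_max_min from any observation
      near <- nearest_match(grid, d$timestamp, gap_max_min * 60)
      filled[is.na(near)] <- NA_real_
      covered <- !is.na(filled)
      interior <- seq_len(1440) >= which(covered)[1] &
        seq_len(1440) <= rev(which(covered))[1]
      filled[!covered] <- 0
      tibble(window_start = grid[seq(1, 1440, by = w_min)],
             sed = colSums(matrix(filled / 40, nrow = w_min)) * 60 / 100,
             partial = any(!covered & interior))
    }) |>
    ungroup()

  per_day |>
    transmute(window_start = .data$window_start, day = .data$day,
              sed = .data$sed, partial = .data$partial)
}

#' Cumulative erythemal dose per day
#'
#' Adds a running cumulative SED column (`csed`) that resets at each
#' station-local day boundary.
#'
#' @param doses A dose tibble from [sed_per_window()] (columns `window_start`,
#'   `day`, `sed`).
#'
#' @return The input with a `csed` column appended.
#' @export
cumulative_sed <- function(doses) {
  if (!all(c("window_start", "day", "sed") %in% names(doses))) {
    abort("`doses` must have columns window_start, day, sed.")
  }
  doses |>
    arrange(.data$window_start) |>
    group_by(.data$day) |>
    mutate(csed = cumsum(.data$sed)) |>
    ungroup()
}

#' Fitzpatrick phototype daily dose thresholds
#'
#' Daily erythemal tolerance thresholds (SED) for the six Fitzpatrick skin
#' phototypes, palest (I) to darkest (VI). These defaults are conventional
#' MED-scale literature values and are plain configuration: pass your own
#' table wherever thresholds are consumed.
#'
#' @param I,II,III,IV,V,VI Threshold in SED per phototype; must be positive
#'   and non-decreasing from I to VI.
#'
#' @return A tibble with columns `phototype` and `threshold_sed`.
#' @export
fitzpatrick_thresholds <- function(I = 2, II = 2.5, III = 3, IV = 4.5,
                                   V = 6, VI = 10) {
  v <- c(I = I, II = II, III = III, IV = IV, V = V, VI = VI)
  if (any(v <= 0)) abort("thresholds must be positive.")
  if (is.unsorted(v)) {
    abort("thresholds must be non-decreasing from phototype I to VI.")
  }
  tibble(phototype = names(v), threshold_sed = unname(v))
}

#' First exceedance of phototype dose thresholds
#'
#' For each station-local day and each phototype, finds the first window at
#' which the cumulative dose reaches the threshold. A zero (or negative)
#' threshold is treated as crossed at the first window with non-zero
#' cumulative dose.
#'
#' @param doses A dose tibble with a `csed` column (see [cumulative_sed()]).
#' @param thresholds A threshold table as from [fitzpatrick_thresholds()].
#'
#' @return A tibble `day` x `phototype` with `threshold_sed`, logical
#'   `crossed`, and `time` (UTC instant of the crossing window, NA when never
#'   crossed).
#' @export
exceedance_time <- function(doses, thresholds = fitzpatrick_thresholds()) {
  if (!"csed" %in% names(doses)) {
    abort("`doses` must carry a `csed` column; run cumulative_sed() first.")
  }
  if (!all(c("phototype", "threshold_sed") %in% names(thresholds))) {
    abort("`thresholds` must have columns phototype, threshold_sed.")
  }
  tidyr::crossing(day = unique(doses$day), thresholds) |>
    rowwise() |>
    mutate(time = {
      d <- doses[doses$day == .data$day, ]
      hit <- if (.data$threshold_sed > 0) {
        which(d$csed >= .data$threshold_sed)
      } else {
        which(d$csed > 0)
      }
      if (length(hit)) d$window_start[hit[1]] else
        lubridate::as_datetime(NA, tz = "UTC")
    }) |>
    ungroup() |>
    mutate(crossed = !is.na(.data$time)) |>
    select("day", "phototype", "threshold_sed", "crossed", "time")
}

who_breaks <- c(0, 3, 6, 8, 11, Inf)
who_labels <- c("low", "moderate", "high", "very_high", "extreme")

#' WHO exposure category of a UVI value
#'
#' Half-open WHO bins with inclusive lower bounds: low \[0, 3), moderate
#' \[3, 6), high \[6, 8), very high \[8, 11), extreme \[11, Inf).
#'
#' @param uvi Non-negative UVI value(s).
#' @return A factor with levels low, moderate, high, very_high, extreme.
#' @examples
#' who_category(c(2, 3, 7.5, 12))
#' @export
who_category <- function(uvi) {
  if (any(uvi < 0, na.rm = TRUE)) abort("`uvi` must be non-negative.")
  cut(uvi, breaks = who_breaks, labels = who_labels, right = FALSE)
}

#' Relative frequency of WHO exposure categories
#'
#' @param uvi Non-empty vector of non-negative UVI values (NAs dropped).
#' @return A tibble `category`, `n`, `frequency`; frequencies sum to 1.
#' @export
category_frequencies <- function(uvi) {
  uvi <- uvi[!is.na(uvi)]
  if (length(uvi) == 0) abort("no UVI values supplied.")
  tab <- table(who_category(uvi))
  tibble(category = factor(names(tab), levels = who_labels),
         n = as.integer(tab),
         frequency = as.integer(tab) / length(uvi))
}
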