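#' Cloud-fraction threshold clear-sky filter (automatic method)
#'
#' Labels each UVI minute `clear` when the matched total cloud fraction is
#' below `cf_threshold` and the solar zenith angle is below `sza_max`;
#' `unknown` when no cloud-fraction sample lies within `match_tol_min`
#' minutes of the UVI minute; `cloudy` otherwise.
#'
#' @param uvi A UVI series tibble (see [uvi_series()]).
#' @param cf A cloud-fraction series tibble (see [cloud_series()]).
#' @param station A [uv_station()], used for the solar-zenith gate.
#' @param cf_threshold Cloud-fraction threshold in \[0, 1\] (default 0.3).
#' @param sza_max Maximum solar zenith angle in degrees, in (0, 90\]
#'   (default 45).
#' @param match_tol_min Matching tolerance between UVI and CF samples,
#'   minutes.
#'
#' @return A sky-mask tibble: `timestamp`, `label` (one of `"clear"`,
#'   `"cloudy"`, `"unknown"`), `method = "AF"`.
#' @export
cf_threshold_filter <- function(uvi, cf, station, cf_threshold = 0.3,
                                sza_max = 45, match_tol_min = 2) {
  assert_uvi_series(uvi)
  assert_cloud_series(cf)
  assert_station(station)
  if (nrow(uvi) == 0 || nrow(cf) == 0) {
    abort("empty series: nothing to filter.")
  }
  if (!is.numeric(cf_threshold) || length(cf_threshold) != 1 ||
      cf_threshold < 0 || cf_threshold > 1) {
    abort("`cf_threshold` must be a single value in [0, 1].")
  }
  if (!is.numeric(sza_max) || length(sza_max) != 1 ||
      sza_max <= 0 || sza_max > 90) {
    abort("`sza_max` must be a single value in (0, 90].")
  }
  idx <- nearest_match(uvi$timestamp, cf$timestamp, match_tol_min * 60)
  cf_here <- cf$cf_total[idx]
  sza <- solar_zenith_angle(station, uvi$timestamp)
  label <- ifelse(is.na(cf_here), "unknown",
                  ifelse(cf_here < cf_threshold & sza < sza_max,
                         "clear", "cloudy"))
  tibble(timestamp = uvi$timestamp, label = label, method = "AF")
}

#' Bell-shape deviation clear-sky filter (manual method, automated)
#'
#' Reproduces, as an explicit rule, the visual inspection that compares a
#' measured daily UVI profile against the bell-shaped analytic clear-sky
#' reference and keeps hour-long stretches that track it. A sliding window of
#' `window` minutes is declared clear when at least `min_frac` of its minutes
#' have relative deviation `|uvi - uvi_cs| / max(uvi_cs, eps) <= rel_tol`;
#' every minute belonging to at least one clear window is labelled `clear`.
#' Minutes where the reference is below `eps` (twilight and night) are
#' `unknown`; remaining minutes are `cloudy`.
#'
#' @param uvi A UVI series tibble.
#' @param reference A clear-sky reference as produced by
#'   [daily_clearsky_profile()] (one or more days bound together); must cover
#'   every timestamp of `uvi`.
#' @param window Window length in minutes (>= 10; default 60).
#' @param rel_tol Relative deviation tolerance (> 0; default 0.10).
#' @param min_frac Minimum fraction of in-tolerance minutes per clear window,
#'   in (0.5, 1\] (default 0.9).
#' @param eps UVI floor below which relative deviation is not evaluated
#'   (default 0.5).
#'
#' @return A sky-mask tibble: `timestamp`, `label`, `method = "MF"`, covering
#'   the timestamps of `uvi`.
#' @export
bell_shape_filter <- function(uvi, reference, window = 60, rel_tol = 0.10,
                              min_frac = 0.9, eps = 0.5) {
  assert_uvi_series(uvi)
  assert_timestamps(reference, "clear-sky reference")
  if (!"uvi_cs" %in% names(reference)) {
    abort("`reference` must have a `uvi_cs` column (see daily_clearsky_profile()).")
  }
  if (!is.numeric(window) || window < 10) abort("`window` must be >= 10 minutes.")
  if (!is.numeric(rel_tol) || rel_tol <= 0) abort("`rel_tol` must be > 0.")
  if (!is.numeric(min_frac) || min_frac <= 0.5 || min_frac > 1) {
    abort("`min_frac` must lie in (0.5, 1].")
  }
  if (!all(uvi$timestamp %in% reference$timestamp)) {
    abort("`reference` does not cover every timestamp of the UVI series (date mismatch).")
  }
  window <- as.integer(round(window))

  grid <- reference |>
    select("timestamp", "uvi_cs") |>
    left_join(select(uvi, "timestamp", "uvi"), by = "timestamp") |>
    mutate(day = lubridate::as_date(.data$timestamp))

  labelled <- grid |>
    group_by(.data$day) |>
    group_modify(~ tibble(
      timestamp = .x$timestamp,
      label = bell_label_day(.x$uvi, .x$uvi_cs, window, rel_tol, min_frac, eps)
    )) |>
    ungroup() |>
    select("timestamp", "label")

  uvi |>
    select("timestamp") |>
    left_join(labelled, by = "timestamp") |>
    mutate(method = "MF")
}

## window logic for one contiguous day of minutes
bell_label_day <- function(uvi, uvi_cs, window, rel_tol, min_frac, eps) {
  n <- length(uvi)
  unknown <- uvi_cs < eps
  ok <- !unknown & !is.na(uvi) &
    abs(uvi - uvi_cs) / pmax(uvi_cs, eps) <= rel_tol
  ok[is.na(ok)] <- FALSE
  clear <- logical(n)
  if (n >= window) {
    csum <- cumsum(c(0, as.numeric(ok)))
    starts <- 1:(n - window + 1)
    frac <- (csum[starts + window] - csum[starts]) / window
    good <- starts[frac >= min_frac]
    if (length(good)) {
      ## mark coverage of all accepted windows via a difference array
      delta <- integer(n + 1)
      delta[good] <- delta[good] + 1L
      delta[good + window] <- delta[good + window] - 1L
      clear <- cumsum(delta[1:n]) > 0
    }
  }
  ifelse(unknown, "unknown", ifelse(clear, "clear", "cloudy"))
}

#' Agreement between two sky masks
#'
#' Fraction of shared timestamps, excluding those labelled `unknown` by
#' either mask, on which the two labels coincide.
#'
#' @param a,b Sky-mask tibbles (`timestamp`, `label`).
#' @param exclude Optional POSIXct instants to leave out of the comparison
#'   (e.g. minutes outside the solar-zenith gate).
#'
#' @return A single fraction in \[0, 1\]; `NaN` when no comparable timestamps
#'   remain.
#' @export
sky_agreement <- function(a, b, exclude = NULL) {
  assert_timestamps(a, "mask `a`")
  assert_timestamps(b, "mask `b`")
  joined <- inner_join(select(a, "timestamp", la = "label"),
                       select(b, "timestamp", lb = "label"),
                       by = "timestamp")
  if (nrow(joined) == 0) abort("the two masks share no timestamps.")
  if (!is.null(exclude)) {
    joined <- filter(joined, !(.data$timestamp %in% exclude))
  }
  joined <- filter(joined, .data$la != "unknown", .data$lb != "unknown")
  mean(joined$la == joined$lb)
}

#' Select the cloud-fraction threshold by agreement maximisation
#'
#' Runs the automatic CF-threshold filter over a grid of candidate thresholds
#' and returns the one whose sky mask agrees best with the bell-shape filter,
#' mirroring how the operational threshold is tuned against the manual
#' method. Agreement is scored over minutes inside the solar-zenith gate
#' (`sza < sza_max`): outside it the threshold filter labels every minute
#' cloudy regardless of the threshold, so those minutes carry no information
#' about the choice. Ties break toward the smaller threshold.
#'
#' @inheritParams cf_threshold_filter
#' @param reference Clear-sky reference passed to [bell_shape_filter()].
#' @param candidate_grid Candidate thresholds in \[0, 1\]
#'   (default 0.05 to 0.95 in steps of 0.05).
#' @param ... Further arguments passed to [bell_shape_filter()].
#'
#' @return A list with elements `cf_threshold` (the selected value),
#'   `agreement` (its score) and `scores` (a tibble over the whole grid).
#' @export
select_cf_threshold <- function(uvi, cf, reference, station,
                                candidate_grid = seq(0.05, 0.95, by = 0.05),
                                sza_max = 45, ...) {
  if (length(candidate_grid) == 0 ||
      any(candidate_grid < 0 | candidate_grid > 1)) {
    abort("`candidate_grid` must be a non-empty set of fractions in [0, 1].")
  }
  mf <- bell_shape_filter(uvi, reference, ...)
  sza <- solar_zenith_angle(station, uvi$timestamp)
  gated_out <- uvi$timestamp[sza >= sza_max]
  scores <- purrr::map_dbl(candidate_grid, function(thr) {
    af <- cf_threshold_filter(uvi, cf, station, cf_threshold = thr,
                              sza_max = sza_max)
    sky_agreement(af, mf, exclude = gated_out)
  })
  if (all(is.nan(scores))) {
    abort("no comparable minutes: both masks are unknown everywhere.")
  }
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  list(cf_threshold = candidate_grid[best],
       agreement = scores[best],
       scores = tibble(cf_threshold = candidate_grid, agreement = scores))
}
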