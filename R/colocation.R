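#' Match ground UVI minutes with satellite/model estimates
#'
#' Applies the space-time colocation rules: an estimate must lie within
#' `max_dist_km` (great-circle, haversine on a 6371 km sphere) of the station
#' and within `max_dt_s` of a ground minute. When several estimates survive
#' for the same ground minute their UVI (and gate quantities) are averaged
#' into a single pair.
#'
#' @param ground A UVI series tibble.
#' @param estimates A tibble of estimate points with columns `timestamp`
#'   (POSIXct UTC), `latitude`, `longitude`, `uvi`, and optionally `source`.
#' @param station A [uv_station()].
#' @param max_dist_km Distance gate in kilometres (> 0; default 10).
#' @param max_dt_s Time gate in seconds (> 0; default 60).
#'
#' @return A tibble of matched pairs: `timestamp` (ground minute),
#'   `ground_uvi`, `estimate_uvi`, `dt_s`, `distance_km`, `n_estimates`.
#'   May be empty.
#' @export
match_estimates <- function(ground, estimates, station,
                            max_dist_km = 10, max_dt_s = 60) {
  assert_uvi_series(ground)
  assert_station(station)
  if (!all(c("timestamp", "latitude", "longitude", "uvi") %in% names(estimates))) {
    abort("`estimates` must have columns timestamp, latitude, longitude, uvi.")
  }
  if (max_dist_km <= 0 || max_dt_s <= 0) {
    abort("`max_dist_km` and `max_dt_s` must be positive.")
  }
  empty <- tibble(timestamp = ground$timestamp[0], ground_uvi = numeric(),
                  estimate_uvi = numeric(), dt_s = numeric(),
                  distance_km = numeric(), n_estimates = integer())
  if (nrow(estimates) == 0 || nrow(ground) == 0) return(empty)

  dist_km <- geosphere::distHaversine(
    cbind(estimates$longitude, estimates$latitude),
    c(station$longitude, station$latitude),
    r = 6371000
  ) / 1000
  est <- estimates |>
    mutate(distance_km = dist_km) |>
    filter(.data$distance_km <= max_dist_km)
  if (nrow(est) == 0) return(empty)

  idx <- nearest_match(est$timestamp, ground$timestamp, max_dt_s)
  est |>
    mutate(g_idx = idx) |>
    filter(!is.na(.data$g_idx)) |>
    mutate(g_time = ground$timestamp[.data$g_idx],
           g_uvi = ground$uvi[.data$g_idx],
           dt_s = as.numeric(.data$timestamp) - as.numeric(.data$g_time)) |>
    filter(!is.na(.data$g_uvi)) |>
    group_by(timestamp = .data$g_time) |>
    summarise(ground_uvi = .data$g_uvi[1],
              estimate_uvi = mean(.data$uvi),
              dt_s = mean(.data$dt_s),
              distance_km = mean(.data$distance_km),
              n_estimates = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$timestamp)
}

#' Split matched pairs by sky condition of the ground minute
#'
#' @param pairs Matched pairs from [match_estimates()].
#' @param mask A sky-mask tibble covering the ground timestamps.
#'
#' @return A list with elements `clear` (pairs whose ground minute is
#'   labelled clear) and `all` (every pair).
#' @export
stratify_by_sky <- function(pairs, mask) {
  assert_timestamps(mask, "sky mask")
  lab <- mask$label[match(pairs$timestamp, mask$timestamp)]
  if (nrow(pairs) && any(is.na(lab))) {
    abort("`mask` does not cover every ground timestamp of `pairs`.")
  }
  list(clear = pairs[!is.na(lab) & lab == "clear", ], all = pairs)
}

#' Ground-versus-estimate difference statistics
#'
#' Computes the standard colocation statistics for a set of matched pairs:
#' absolute differences AD = estimate - ground (UVI units), relative
#' differences RD = 100 (estimate - ground) / ground (percent), their means,
#' standard deviations and medians, plus the Pearson correlation `r` and its
#' square `r2`. Pairs with ground UVI below `rd_floor` are excluded from the
#' RD statistics only (relative differences diverge at twilight).
#'
#' @param pairs Matched pairs from [match_estimates()] (columns `ground_uvi`,
#'   `estimate_uvi`); at least one row.
#' @param rd_floor Minimum ground UVI for a pair to enter the RD statistics.
#'
#' @return An object of class `uv_comparison`. Use [tidy()] for a long
#'   statistic table and [glance()] for a one-row summary.
#' @examples
#' pairs <- tibble::tibble(ground_uvi = c(10, 5), estimate_uvi = c(11, 5.5))
#' glance(compare_pairs(pairs))
#' @export
compare_pairs <- function(pairs, rd_floor = 0.5) {
  if (!all(c("ground_uvi", "estimate_uvi") %in% names(pairs))) {
    abort("`pairs` must have columns ground_uvi and estimate_uvi.")
  }
  if (nrow(pairs) == 0) abort("`pairs` is empty: nothing to compare.")
  ad <- pairs$estimate_uvi - pairs$ground_uvi
  rd_ok <- pairs$ground_uvi >= rd_floor
  rd <- 100 * ad[rd_ok] / pairs$ground_uvi[rd_ok]
  n <- nrow(pairs)
  r <- if (n >= 2 && sd(pairs$ground_uvi) > 0 && sd(pairs$estimate_uvi) > 0) {
    cor(pairs$ground_uvi, pairs$estimate_uvi)
  } else {
    NA_real_
  }
  structure(
    list(stats = tibble(
      n = n, n_rd = sum(rd_ok),
      mean_ad = mean(ad), sd_ad = sd(ad), median_ad = median(ad),
      mean_rd = mean(rd), sd_rd = sd(rd), median_rd = median(rd),
      r = r, r2 = r^2
    ), pairs = as_tibble(pairs), rd_floor = rd_floor),
    class = "uv_comparison"
  )
}

#' @export
print.uv_comparison <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<uv_comparison> n = %d pairs (%d in RD stats, floor %.2g UVI)\n",
              s$n, s$n_rd, x$rd_floor))
  cat(sprintf("  mean AD %.2f +/- %.2f UVI, median AD %.2f UVI\n",
              s$mean_ad, s$sd_ad, s$median_ad))
  cat(sprintf("  mean RD %.1f +/- %.1f %%, median RD %.1f %%\n",
              s$mean_rd, s$sd_rd, s$median_rd))
  cat(sprintf("  r = %.3f, r2 = %.3f\n", s$r, s$r2))
  invisible(x)
}

#' @rdname compare_pairs
#' @param x A `uv_comparison` object.
#' @param ... Unused.
#' @method tidy uv_comparison
#' @export
tidy.uv_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$stats, dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @rdname compare_pairs
#' @method glance uv_comparison
#' @export
glance.uv_comparison <- function(x, ...) {
  x$stats
}

#' Side-by-side comparison table across sources and sky strata
#'
#' Convenience wrapper assembling one [compare_pairs()] column per named set
#' of pairs, mirroring the usual validation-table layout (rows: statistics,
#' columns: source x sky condition).
#'
#' @param ... Named matched-pair tibbles (e.g. `TROPOMI_clear = ...`).
#' @param rd_floor Passed to [compare_pairs()].
#' @return A tibble with a `statistic` column and one column per input.
#' @export
comparison_table <- function(..., rd_floor = 0.5) {
  sets <- list(...)
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == "")) {
    abort("supply named matched-pair tibbles.")
  }
  purrr::imap(sets, function(p, nm) {
    tidy(compare_pairs(p, rd_floor = rd_floor)) |>
      rename(!!nm := "value")
  }) |>
    purrr::reduce(left_join, by = "statistic")
}
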