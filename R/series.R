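#' Build a UVI time series
#'
#' Light-weight constructor/validator for the minute-resolution UVI tables the
#' package operates on: a tibble with a strictly increasing `timestamp`
#' column (POSIXct, UTC), a non-negative `uvi` column, a `source` tag and an
#' optional per-sample `flag`.
#'
#' @param timestamp POSIXct vector (UTC), strictly increasing.
#' @param uvi Non-negative UVI values (NA allowed for flagged gaps).
#' @param source Single tag naming the instrument or product
#'   (e.g. "RADIO", "TROPOMI", "CAMS", "TUV", "HIKE").
#' @param flag Optional character vector of quality marks.
#'
#' @return A tibble with columns `timestamp`, `uvi`, `source`, `flag`.
#' @export
uvi_series <- function(timestamp, uvi, source = "RADIO", flag = NA_character_) {
  x <- tibble(timestamp = timestamp, uvi = as.numeric(uvi),
              source = as.character(source),
              flag = as.character(flag))
  assert_uvi_series(x)
  x
}

#' Build a cloud-fraction time series
#'
#' @param timestamp POSIXct vector (UTC), strictly increasing.
#' @param cf_total,cf_thick,cf_thin Sky fractions in \[0, 1\]. The thick and
#'   thin components may not exceed the total by more than 0.05 (retrieval
#'   noise tolerance).
#'
#' @return A tibble with columns `timestamp`, `cf_total`, `cf_thick`,
#'   `cf_thin`.
#' @export
cloud_series <- function(timestamp, cf_total, cf_thick = 0, cf_thin = 0) {
  x <- tibble(timestamp = timestamp, cf_total = as.numeric(cf_total),
              cf_thick = as.numeric(cf_thick), cf_thin = as.numeric(cf_thin))
  assert_cloud_series(x)
  x
}

assert_timestamps <- function(x, what = "series") {
  if (!is.data.frame(x) || !"timestamp" %in% names(x)) {
    abort(sprintf("%s must be a data frame with a `timestamp` column.", what))
  }
  if (!inherits(x$timestamp, "POSIXct")) {
    abort(sprintf("%s `timestamp` must be POSIXct (UTC).", what))
  }
  if (any(is.na(x$timestamp))) {
    abort(sprintf("%s `timestamp` contains missing values.", what))
  }
  dt <- diff(as.numeric(x$timestamp))
  if (length(dt) && any(dt <= 0)) {
    abort(sprintf("%s timestamps must be strictly increasing (first violation at row %d).",
                  what, which(dt <= 0)[1] + 1L))
  }
  invisible(x)
}

assert_uvi_series <- function(x) {
  assert_timestamps(x, "UVI series")
  if (!"uvi" %in% names(x)) abort("UVI series must have a `uvi` column.")
  if (any(x$uvi < 0, na.rm = TRUE)) abort("`uvi` values must be non-negative.")
  invisible(x)
}

assert_cloud_series <- function(x) {
  assert_timestamps(x, "cloud series")
  need <- c("cf_total", "cf_thick", "cf_thin")
  if (!all(need %in% names(x))) {
    abort("cloud series must have columns cf_total, cf_thick, cf_thin.")
  }
  for (col in need) {
    v <- x[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(sprintf("`%s` must lie in [0, 1].", col))
    }
  }
  excess <- x$cf_thick + x$cf_thin - x$cf_total
  if (any(excess > 0.05, na.rm = TRUE)) {
    abort("cf_thick + cf_thin exceeds cf_total by more than the 0.05 tolerance.")
  }
  invisible(x)
}

## nearest-neighbour match of `target` instants into sorted `pool` instants;
## returns index into pool or NA when nothing lies within `tol_s` seconds
nearest_match <- function(target, pool, tol_s) {
  tn <- as.numeric(target)
  pn <- as.numeric(pool)
  idx <- findInterval(tn, pn)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(pn))
  d_lo <- abs(tn - pn[lo])
  d_hi <- abs(tn - pn[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  ifelse(dist <= tol_s, best, NA_integer_)
}
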