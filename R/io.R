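#' Read and write minute-series CSV tables
#'
#' All persistent tables share one layout: a header row, an ISO-8601 UTC
#' `timestamp` column, named numeric value columns, and empty fields for
#' missing values. Timestamps must parse and be strictly increasing;
#' violations raise an error naming the first offending row. Writing then
#' reading reproduces timestamps exactly and values to better than 1e-9.
#'
#' `read_uvi_series()`, `read_cloud_series()`, `read_estimates()` and
#' `read_toc()` wrap [read_series()] with the schema each pipeline stage
#' expects.
#'
#' @param path File path.
#' @param columns Named character vector of expected value columns and their
#'   readr types (e.g. `c(uvi = "d")`); columns not listed are rejected.
#' @param optional Names of `columns` that may be absent from the file.
#'
#' @return A tibble with a POSIXct UTC `timestamp` column.
#' @export
read_series <- function(path, columns, optional = character()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE, show_col_types = FALSE)
  if (!"timestamp" %in% names(x)) {
    abort(sprintf("%s: missing `timestamp` column.", path))
  }
  unknown <- setdiff(names(x), c("timestamp", names(columns)))
  if (length(unknown)) {
    abort(sprintf("%s: unknown column(s): %s", path,
                  paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(setdiff(names(columns), optional), names(x))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.character(x$timestamp)) {
    parsed <- lubridate::ymd_hms(x$timestamp, tz = "UTC", quiet = TRUE)
  } else if (inherits(x$timestamp, "POSIXct")) {
    parsed <- lubridate::with_tz(x$timestamp, "UTC")
  } else {
    parsed <- lubridate::as_datetime(NA)[seq_len(nrow(x))]
  }
  if (anyNA(parsed)) {
    abort(sprintf("%s: malformed timestamp at row %d.",
                  path, which(is.na(parsed))[1]))
  }
  x$timestamp <- parsed
  dt <- diff(as.numeric(parsed))
  if (length(dt) && any(dt <= 0)) {
    abort(sprintf("%s: timestamps not strictly increasing at row %d.",
                  path, which(dt <= 0)[1] + 1L))
  }
  for (col in intersect(names(columns), names(x))) {
    x[[col]] <- if (columns[[col]] == "c") as.character(x[[col]]) else
      as.numeric(x[[col]])
  }
  as_tibble(x)
}

#' @rdname read_series
#' @export
read_uvi_series <- function(path) {
  x <- read_series(path, columns = c(uvi = "d", source = "c", flag = "c"),
                   optional = c("source", "flag"))
  if (!"source" %in% names(x)) x$source <- "RADIO"
  if (!"flag" %in% names(x)) x$flag <- NA_character_
  assert_uvi_series(x)
  x
}

#' @rdname read_series
#' @export
read_cloud_series <- function(path) {
  x <- read_series(path, columns = c(cf_total = "d", cf_thick = "d",
                                     cf_thin = "d"),
                   optional = c("cf_thick", "cf_thin"))
  if (!"cf_thick" %in% names(x)) x$cf_thick <- 0
  if (!"cf_thin" %in% names(x)) x$cf_thin <- 0
  assert_cloud_series(x)
  x
}

#' @rdname read_series
#' @export
read_estimates <- function(path) {
  read_series(path, columns = c(latitude = "d", longitude = "d", uvi = "d",
                                source = "c", sky = "c"),
              optional = c("source", "sky"))
}

#' @rdname read_series
#' @export
read_toc <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("date", "toc") %in% names(x))) {
    abort(sprintf("%s: TOC table must have columns date, toc.", path))
  }
  x$date <- lubridate::as_date(x$date)
  if (anyNA(x$date)) {
    abort(sprintf("%s: malformed date at row %d.", path,
                  which(is.na(x$date))[1]))
  }
  if (any(x$toc <= 0, na.rm = TRUE)) {
    abort(sprintf("%s: TOC values must be positive.", path))
  }
  as_tibble(x)
}

#' @rdname read_series
#' @param x A tibble with a POSIXct `timestamp` column (or a `date` column
#'   for TOC tables).
#' @export
write_series <- function(x, path) {
  out <- x
  if ("timestamp" %in% names(out)) {
    out$timestamp <- format(lubridate::with_tz(out$timestamp, "UTC"),
                            "%Y-%m-%dT%H:%M:%SZ")
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Load a synthetic-generator configuration from YAML
#'
#' Reads a YAML mapping whose keys are the arguments of
#' [synthetic_config()] (plus an optional nested `station` mapping with keys
#' `latitude`, `longitude`, `altitude_km`, `utc_offset`, `name`). Unknown
#' keys are rejected by name; `seed` is mandatory.
#'
#' @param path Path to the YAML file.
#' @return A [synthetic_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort(sprintf("%s: expected a YAML mapping.", path))
  allowed <- setdiff(names(formals(synthetic_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(sprintf("%s: unknown configuration key(s): %s", path,
                  paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$seed)) {
    abort(sprintf("%s: `seed` is mandatory in a simulation config.", path))
  }
  if (!is.null(raw$station)) {
    raw$station <- do.call(uv_station, raw$station)
  }
  if (!is.null(raw$start_date)) raw$start_date <- lubridate::as_date(raw$start_date)
  if (!is.null(raw$cloudy_cf_range)) {
    raw$cloudy_cf_range <- as.numeric(raw$cloudy_cf_range)
  }
  do.call(synthetic_config, raw)
}
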