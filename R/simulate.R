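#' Configuration for the synthetic station generator
#'
#' Defines the study conditions the generator emulates: a tropical island
#' station with a diurnal cloud cycle (total cloud fraction around 0.55 at
#' dawn, a slight morning dip, a maximum near 0.8 around 17:00 local time,
#' and a thin-cloud deck of about 0.15 appearing from 08:00), wet
#' (November-April) and dry (May-October) season cloudiness, a sinusoidal
#' total-ozone annual cycle, cloud attenuation with occasional broken-cloud
#' enhancement, multiplicative sensor noise, and biased, noisy satellite or
#' model estimate streams.
#'
#' @param station A [uv_station()] (default [moroni_station()]).
#' @param start_date First station-local date simulated.
#' @param n_days Number of consecutive days.
#' @param seed Integer seed; mandatory, every stochastic draw derives from it.
#' @param toc_mean,toc_amplitude Mean and annual amplitude of the total ozone
#'   column (Dobson units).
#' @param cloud_model `"diurnal"` for the smooth diurnal-cycle process with
#'   AR(1) noise, `"separated"` for well-separated clear/cloudy regimes in
#'   persistent blocks.
#' @param cf_noise_sd Marginal sd of the AR(1) cloud-fraction noise.
#' @param cf_ar1 AR(1) persistence coefficient of the cloud-fraction noise.
#' @param wet_multiplier,dry_multiplier Seasonal multipliers on the baseline
#'   cloud fraction (wet: November-April).
#' @param thin_cf Thin-cloud fraction present from 08:00 local time.
#' @param label_threshold True-label rule: a minute is truly clear when
#'   `cf_total < label_threshold`.
#' @param block_min Regime block length (minutes) in `"separated"` mode.
#' @param p_clear_block Probability a block is clear in `"separated"` mode.
#' @param clear_cf_max,cloudy_cf_range CF ranges of the two separated regimes.
#' @param cmf_a,cmf_b Cloud modification `cmf = 1 - cmf_a * cf^cmf_b` for
#'   non-enhanced minutes (full overcast removes `cmf_a` of the index).
#' @param p_enhance Probability of broken-cloud enhancement on minutes with
#'   CF in (0.2, 0.7).
#' @param enhance_max Maximum enhancement factor (cmf drawn in
#'   (1, enhance_max\]).
#' @param sensor_noise_sd Multiplicative sensor noise sd.
#' @param altitude_rate Altitude gradient (fraction per km) used for clear-sky
#'   profiles and hikes.
#' @param sky_factor Constant aerosol/albedo factor for clear-sky profiles.
#'
#' @return A named list of class `synthetic_config`.
#' @export
synthetic_config <- function(station = moroni_station(),
                             start_date = as.Date("2020-01-01"),
                             n_days = 30,
                             seed,
                             toc_mean = 260, toc_amplitude = 15,
                             cloud_model = c("diurnal", "separated"),
                             cf_noise_sd = 0.12, cf_ar1 = 0.995,
                             wet_multiplier = 1.15, dry_multiplier = 0.85,
                             thin_cf = 0.15,
                             label_threshold = 0.2,
                             block_min = 180, p_clear_block = 0.5,
                             clear_cf_max = 0.1, cloudy_cf_range = c(0.5, 0.95),
                             cmf_a = 0.75, cmf_b = 2,
                             p_enhance = 0.05, enhance_max = 1.2,
                             sensor_noise_sd = 0.02,
                             altitude_rate = 0.06, sky_factor = 1) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || is.na(seed)) {
    abort("`seed` is mandatory for the synthetic generator.")
  }
  assert_station(station)
  cloud_model <- match.arg(cloud_model)
  probs <- c(p_clear_block = p_clear_block, p_enhance = p_enhance,
             label_threshold = label_threshold, clear_cf_max = clear_cf_max)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities and CF thresholds must lie in [0, 1].")
  }
  if (enhance_max < 1) abort("`enhance_max` must be >= 1.")
  cfg <- list(
    station = station, start_date = lubridate::as_date(start_date),
    n_days = as.integer(n_days), seed = as.integer(seed),
    toc_mean = toc_mean, toc_amplitude = toc_amplitude,
    cloud_model = cloud_model, cf_noise_sd = cf_noise_sd, cf_ar1 = cf_ar1,
    wet_multiplier = wet_multiplier, dry_multiplier = dry_multiplier,
    thin_cf = thin_cf, label_threshold = label_threshold,
    block_min = as.integer(block_min), p_clear_block = p_clear_block,
    clear_cf_max = clear_cf_max, cloudy_cf_range = cloudy_cf_range,
    cmf_a = cmf_a, cmf_b = cmf_b,
    p_enhance = p_enhance, enhance_max = enhance_max,
    sensor_noise_sd = sensor_noise_sd,
    altitude_rate = altitude_rate, sky_factor = sky_factor
  )
  structure(cfg, class = "synthetic_config")
}

## per-day deterministic sub-seed, kept inside 32-bit integer range
day_seed <- function(config, date, salt = 0L) {
  as.integer((as.numeric(config$seed) + 7919 * (as.numeric(date) %% 100000) +
                104729 * salt) %% .Machine$integer.max)
}

#' Daily total ozone column of the synthetic annual cycle
#'
#' @param config A [synthetic_config()].
#' @param date Date vector.
#' @return TOC in Dobson units.
#' @export
synthetic_toc <- function(config, date) {
  doy <- lubridate::yday(lubridate::as_date(date))
  config$toc_mean +
    config$toc_amplitude * cos(2 * pi * (doy - 15) / 365.25)
}

## diurnal baseline cloud fraction by local minute-of-day: ~0.55 at dawn,
## a morning dip, rising to ~0.8 at 17:00 local
cloud_baseline <- function(minute_of_day) {
  h <- minute_of_day / 60
  knots_h <- c(0, 6, 9.5, 13, 17, 20, 24)
  knots_cf <- c(0.55, 0.55, 0.45, 0.62, 0.80, 0.65, 0.55)
  approx(knots_h, knots_cf, xout = h, method = "linear", rule = 2)$y
}

season_multiplier <- function(config, date) {
  m <- lubridate::month(lubridate::as_date(date))
  if (m >= 11 || m <= 4) config$wet_multiplier else config$dry_multiplier
}

#' Generate one synthetic day of cloud fractions
#'
#' In `"diurnal"` mode the total cloud fraction is the seasonal diurnal
#' baseline plus stationary AR(1) noise, clipped to \[0, 1\]. In
#' `"separated"` mode the day is split into persistent blocks that are
#' either clear (CF uniform below `clear_cf_max`) or cloudy (CF uniform in
#' `cloudy_cf_range`), giving well-separated regimes. Thin cloud sits at a
#' constant `thin_cf` from 08:00 local time; thick cloud is the remainder.
#'
#' @param config A [synthetic_config()].
#' @param date Station-local date.
#' @param seed Optional integer overriding the config-derived per-day seed.
#'
#' @return A list with `cf` (a [cloud_series()] tibble, 1440 minutes) and
#'   `labels` (tibble `timestamp`, `label` with the true clear/cloudy state).
#' @export
generate_cloud_day <- function(config, date, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  date <- lubridate::as_date(date)
  seed <- seed %||% day_seed(config, date, salt = 1L)
  minutes <- day_minute_grid(config$station, date)
  mod <- 0:1439

  cf_total <- withr::with_seed(seed, {
    if (config$cloud_model == "diurnal") {
      base <- cloud_baseline(mod) * season_multiplier(config, date)
      e <- numeric(1440)
      innov_sd <- config$cf_noise_sd * sqrt(1 - config$cf_ar1^2)
      e[1] <- rnorm(1, 0, config$cf_noise_sd)
      z <- rnorm(1439, 0, innov_sd)
      for (i in 2:1440) e[i] <- config$cf_ar1 * e[i - 1] + z[i - 1]
      pmin(pmax(base + e, 0), 1)
    } else {
      n_blocks <- ceiling(1440 / config$block_min)
      clear_block <- runif(n_blocks) < config$p_clear_block
      state <- rep(clear_block, each = config$block_min)[1:1440]
      ifelse(state,
             runif(1440, 0, config$clear_cf_max),
             runif(1440, config$cloudy_cf_range[1], config$cloudy_cf_range[2]))
    }
  })

  thin <- ifelse(mod >= 8 * 60, pmin(config$thin_cf, cf_total), 0)
  cf <- tibble(timestamp = minutes, cf_total = cf_total,
               cf_thick = pmax(cf_total - thin, 0), cf_thin = thin)
  labels <- tibble(timestamp = minutes,
                   label = ifelse(cf_total < config$label_threshold,
                                  "clear", "cloudy"))
  list(cf = cf, labels = labels)
}

#' Generate one synthetic day of all-sky UVI with known truth
#'
#' Builds the clear-sky profile for the day's TOC and station altitude, then
#' applies a cloud modification factor per minute: `1 - cmf_a * cf^cmf_b`
#' for ordinary minutes, or an enhancement factor drawn in
#' `(1, enhance_max]` with probability `p_enhance` on broken-cloud minutes
#' (CF in (0.2, 0.7)). Multiplicative sensor noise is added and the result
#' clamped to `[0, uvi_cs * enhance_max]`.
#'
#' @inheritParams generate_cloud_day
#' @param cloud Output of [generate_cloud_day()] for the same date (generated
#'   if omitted).
#'
#' @return A truth bundle: list with `uvi` (all-sky series), `uvi_cs`
#'   (clear-sky reference tibble), `cf`, `labels`, `cmf` (numeric vector),
#'   `toc` and `date`.
#' @export
generate_uvi_day <- function(config, date, cloud = NULL, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  date <- lubridate::as_date(date)
  cloud <- cloud %||% generate_cloud_day(config, date)
  seed <- seed %||% day_seed(config, date, salt = 2L)
  toc <- synthetic_toc(config, date)
  ref <- daily_clearsky_profile(config$station, date, toc,
                                rate = config$altitude_rate,
                                sky_factor = config$sky_factor)
  cf <- cloud$cf$cf_total
  out <- withr::with_seed(seed, {
    cmf <- 1 - config$cmf_a * cf^config$cmf_b
    broken <- cf > 0.2 & cf < 0.7
    enh <- broken & runif(1440) < config$p_enhance
    cmf[enh] <- runif(sum(enh), 1, config$enhance_max)
    noise <- 1 + rnorm(1440, 0, config$sensor_noise_sd)
    uvi <- pmin(pmax(ref$uvi_cs * cmf * noise, 0),
                ref$uvi_cs * config$enhance_max)
    list(cmf = cmf, uvi = uvi)
  })
  list(
    uvi = tibble(timestamp = ref$timestamp, uvi = out$uvi,
                 source = "SYNTH", flag = NA_character_),
    uvi_cs = ref, cf = cloud$cf, labels = cloud$labels,
    cmf = out$cmf, toc = toc, date = date
  )
}

#' Simulate a multi-day synthetic station record
#'
#' @param config A [synthetic_config()].
#' @return A list of bound tibbles: `uvi`, `uvi_cs`, `cf`, `labels`, and a
#'   per-day `toc` table.
#' @export
simulate_station <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dates <- config$start_date + seq_len(config$n_days) - 1
  days <- purrr::map(dates, function(d) generate_uvi_day(config, d))
  list(
    uvi = purrr::list_rbind(purrr::map(days, "uvi")),
    uvi_cs = purrr::list_rbind(purrr::map(days, "uvi_cs")),
    cf = purrr::list_rbind(purrr::map(days, "cf")),
    labels = purrr::list_rbind(purrr::map(days, "labels")),
    toc = tibble(date = dates, toc = purrr::map_dbl(days, "toc"))
  )
}

#' Generate a synthetic mountain-hike UVI record
#'
#' Samples the station day's all-sky UVI along an altitude profile (default
#' every 10 minutes) and scales each sample by the ratio of the altitude
#' adjustment at the walker's altitude to that at the station altitude.
#'
#' @param config A [synthetic_config()].
#' @param altitude_profile A tibble with columns `timestamp` (POSIXct UTC)
#'   and `altitude_km`.
#' @param seed Optional integer seed override for the underlying day.
#'
#' @return A UVI series tibble with an `altitude_km` column,
#'   `source = "HIKE"`.
#' @export
generate_hike <- function(config, altitude_profile, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_timestamps(altitude_profile, "altitude profile")
  if (!"altitude_km" %in% names(altitude_profile)) {
    abort("`altitude_profile` must have an `altitude_km` column.")
  }
  date <- local_date(altitude_profile$timestamp[1], config$station)
  day <- generate_uvi_day(config, date, seed = seed)
  idx <- nearest_match(altitude_profile$timestamp, day$uvi$timestamp, 60)
  if (any(is.na(idx))) {
    abort("altitude profile extends outside the simulated day.")
  }
  base_factor <- 1 + config$altitude_rate * config$station$altitude_km
  factor <- (1 + config$altitude_rate * altitude_profile$altitude_km) /
    base_factor
  tibble(timestamp = altitude_profile$timestamp,
         uvi = day$uvi$uvi[idx] * factor,
         source = "HIKE", flag = NA_character_,
         altitude_km = altitude_profile$altitude_km)
}

#' Generate satellite or model estimate points from a truth bundle
#'
#' Satellite mode emits one estimate per day at local solar noon plus
#' `overpass_offset_min`; model mode emits one estimate at each fixed UTC
#' forecast hour. Each estimate is the truth smoothed over +/-
#' `smooth_min` minutes (a surrogate for the pixel-scale mismatch between a
#' large footprint and a point measurement), times `bias`, times
#' multiplicative noise; coordinates are jittered uniformly within
#' `jitter_km` of the station.
#'
#' @param truth Output of [simulate_station()] (or a single-day bundle with
#'   the same element names plus `labels`).
#' @param config The [synthetic_config()] used to build `truth`.
#' @param source Tag for the estimate stream.
#' @param bias Multiplicative bias.
#' @param noise_sd Multiplicative noise sd.
#' @param mode `"satellite"` (one point per day) or `"model"` (fixed UTC
#'   forecast hours).
#' @param overpass_offset_min Satellite overpass delay after local solar
#'   noon, minutes.
#' @param forecast_hours_utc UTC hours sampled in model mode.
#' @param smooth_min Half-width of the smoothing window, minutes (0 disables
#'   smoothing).
#' @param smooth_cloudy_only If TRUE, smoothing is applied only where the
#'   true sky label is cloudy (clear minutes keep the instantaneous truth),
#'   emulating estimates that err mostly under broken cloud.
#' @param jitter_km Maximum coordinate jitter, km.
#' @param seed Optional integer seed override.
#'
#' @return A tibble of estimate points: `timestamp`, `latitude`,
#'   `longitude`, `uvi`, `source`, `sky`.
#' @export
generate_estimates <- function(truth, config, source = "SAT", bias = 1,
                               noise_sd = 0, mode = c("satellite", "model"),
                               overpass_offset_min = 60,
                               forecast_hours_utc = c(5, 7, 9, 11),
                               smooth_min = 15, smooth_cloudy_only = FALSE,
                               jitter_km = 5, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  uvi <- truth$uvi
  assert_uvi_series(uvi)
  seed <- seed %||% day_seed(config, config$start_date, salt = 3L)
  days <- sort(unique(local_date(uvi$timestamp, config$station)))

  target <- if (mode == "satellite") {
    as.numeric(local_solar_noon(config$station, days)) +
      overpass_offset_min * 60
  } else {
    as.vector(outer(forecast_hours_utc * 3600,
                    as.numeric(lubridate::as_datetime(days, tz = "UTC")), `+`))
  }
  target <- lubridate::as_datetime(sort(target), tz = "UTC")

  ## smoothed truth: centred rolling mean over +/- smooth_min minutes
  smoothed <- if (smooth_min > 0) {
    k <- 2 * as.integer(smooth_min) + 1
    pad <- stats::filter(uvi$uvi, rep(1 / k, k), sides = 2)
    out <- as.numeric(pad)
    out[is.na(out)] <- uvi$uvi[is.na(out)]
    out
  } else {
    uvi$uvi
  }
  if (smooth_cloudy_only) {
    lab <- truth$labels$label[match(uvi$timestamp, truth$labels$timestamp)]
    smoothed[!is.na(lab) & lab == "clear"] <-
      uvi$uvi[!is.na(lab) & lab == "clear"]
  }

  idx <- nearest_match(target, uvi$timestamp, 60)
  keep <- !is.na(idx)
  target <- target[keep]; idx <- idx[keep]

  withr::with_seed(seed, {
    n <- length(target)
    est <- smoothed[idx] * bias * (1 + rnorm(n, 0, noise_sd))
    ## ~111 km per degree latitude; shrink longitude jitter by cos(lat)
    dlat <- runif(n, -1, 1) * jitter_km / 111.2
    dlon <- runif(n, -1, 1) * jitter_km / 111.2 /
      cos(config$station$latitude * pi / 180)
    tibble(timestamp = target,
           latitude = config$station$latitude + dlat,
           longitude = config$station$longitude + dlon,
           uvi = pmax(est, 0),
           source = source, sky = "all")
  })
}
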