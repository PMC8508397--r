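st_moroni <- moroni_station()
jan12 <- as.Date("2020-01-12")

make_day <- function(cf_total, uvi = NULL, station = st_moroni, date = jan12) {
  ref <- daily_clearsky_profile(station, date, 260)
  if (is.null(uvi)) uvi <- ref$uvi_cs
  list(
    uvi = grid_series(station, date, uvi),
    cf = cloud_series(ref$timestamp, cf_total,
                      cf_thick = pmax(cf_total - 0.05, 0),
                      cf_thin = pmin(cf_total, 0.05)),
    ref = ref
  )
}

test_that("CF-threshold filter gates on cloud fraction and solar zenith angle", {
  d <- make_day(cf_total = rep(0, 1440))
  mask <- cf_threshold_filter(d$uvi, d$cf, st_moroni, cf_threshold = 0.3,
                              sza_max = 45)
  sza <- solar_zenith_angle(st_moroni, d$uvi$timestamp)
  expect_identical(mask$label, ifelse(sza < 45, "clear", "cloudy"))

  d1 <- make_day(cf_total = rep(1, 1440))
  mask1 <- cf_threshold_filter(d1$uvi, d1$cf, st_moroni)
  expect_false(any(mask1$label == "clear"))

  # no CF sample within the matching tolerance -> unknown
  cf_sparse <- d$cf[seq(1, 1440, by = 30), ]
  mask_sp <- cf_threshold_filter(d$uvi, cf_sparse, st_moroni)
  expect_true(any(mask_sp$label == "unknown"))
  dist_min <- abs(as.numeric(d$uvi$timestamp) -
                    as.numeric(cf_sparse$timestamp[
                      erythemal:::nearest_match(d$uvi$timestamp,
                                                cf_sparse$timestamp, Inf)])) / 60
  expect_identical(mask_sp$label == "unknown", dist_min > 2)
})

test_that("CF step day matches an exhaustive per-minute oracle", {
  cf_step <- c(rep(0, 720), rep(0.5, 720))  # 0 before local noon, 0.5 after
  d <- make_day(cf_total = cf_step)
  mask <- cf_threshold_filter(d$uvi, d$cf, st_moroni, cf_threshold = 0.3)
  sza <- solar_zenith_angle(st_moroni, d$uvi$timestamp)
  oracle <- vapply(seq_len(1440), function(i) {
    if (cf_step[i] < 0.3 && sza[i] < 45) "clear" else "cloudy"
  }, character(1))
  expect_identical(mask$label, oracle)
  expect_true(any(mask$label == "clear"))
  # clear labels confined to the morning (local) half of the day
  clear_min <- which(mask$label == "clear")
  expect_true(all(clear_min <= 720))
})

test_that("raising the CF threshold never removes a clear label", {
  set.seed(11)
  cf_rand <- runif(1440)
  d <- make_day(cf_total = cf_rand)
  masks <- lapply(seq(0.1, 0.9, by = 0.2), function(thr) {
    cf_threshold_filter(d$uvi, d$cf, st_moroni, cf_threshold = thr)
  })
  for (i in seq_along(masks)[-1]) {
    prev_clear <- masks[[i - 1]]$timestamp[masks[[i - 1]]$label == "clear"]
    this_clear <- masks[[i]]$timestamp[masks[[i]]$label == "clear"]
    expect_true(all(prev_clear %in% this_clear))
  }
})

test_that("bell-shape filter keeps profiles that track the reference", {
  d <- make_day(cf_total = rep(0, 1440))

  # measured identical to reference: every reference-covered minute is clear
  mask <- bell_shape_filter(d$uvi, d$ref)
  expect_true(all(mask$label[d$ref$uvi_cs >= 0.5] == "clear"))
  expect_true(all(mask$label[d$ref$uvi_cs < 0.5] == "unknown"))

  # heavy uniform attenuation: nothing survives
  d3 <- make_day(cf_total = rep(0, 1440), uvi = 0.3 * d$ref$uvi_cs)
  mask3 <- bell_shape_filter(d3$uvi, d$ref, rel_tol = 0.1)
  expect_false(any(mask3$label == "clear"))

  expect_error(
    bell_shape_filter(grid_series(st_moroni, jan12 + 30, d$ref$uvi_cs), d$ref),
    "cover"
  )
})

test_that("bell-shape filter recovers a planted clear interval", {
  ref <- daily_clearsky_profile(st_moroni, jan12, 260)
  lt_min <- erythemal:::local_minute_of_day(ref$timestamp, st_moroni)
  truth_clear <- lt_min >= 9 * 60 & lt_min < 11 * 60
  set.seed(42)
  atten <- ifelse(truth_clear, 1, runif(1440, 0.2, 0.6))
  uvi <- ref$uvi_cs * atten * (1 + rnorm(1440, 0, 0.01))
  mask <- bell_shape_filter(grid_series(st_moroni, jan12, pmax(uvi, 0)), ref)
  got <- mask$label == "clear"
  daylight <- ref$uvi_cs >= 0.5
  jaccard <- sum(got & truth_clear & daylight) /
    sum((got | truth_clear) & daylight)
  expect_gte(jaccard, 0.8)
})

test_that("mask agreement counts comparable minutes symmetrically", {
  ts <- utc("2020-01-01 00:00:00") + 0:99 * 60
  a <- tibble::tibble(timestamp = ts, label = rep("clear", 100), method = "AF")
  expect_equal(sky_agreement(a, a), 1)

  b <- a
  b$label <- "cloudy"
  expect_equal(sky_agreement(a, b), 0)

  # differ on 3 of 100 comparable minutes
  b2 <- a
  b2$label[1:3] <- "cloudy"
  expect_equal(sky_agreement(a, b2), 0.97)
  expect_equal(sky_agreement(b2, a), sky_agreement(a, b2))

  # unknown minutes are excluded from the denominator
  b3 <- a
  b3$label[1:50] <- "unknown"
  b3$label[51] <- "cloudy"
  expect_equal(sky_agreement(a, b3), 49 / 50)

  expect_error(sky_agreement(a, dplyr::mutate(a, timestamp = timestamp + 7)),
               "share no timestamps")
})

test_that("threshold selection maximises agreement with the bell filter", {
  d <- make_day(cf_total = rep(0, 1440))

  # single-value grid is returned untouched
  sel1 <- select_cf_threshold(d$uvi, d$cf, d$ref, st_moroni,
                              candidate_grid = 0.4)
  expect_equal(sel1$cf_threshold, 0.4)

  # degenerate all-clear day: every threshold ties, smallest wins
  sel <- select_cf_threshold(d$uvi, d$cf, d$ref, st_moroni,
                             candidate_grid = seq(0.05, 0.95, 0.05))
  expect_equal(sel$cf_threshold, 0.05)
  expect_equal(max(sel$scores$agreement), sel$agreement)

  expect_error(
    select_cf_threshold(d$uvi, d$cf, d$ref, st_moroni, candidate_grid = 1.5),
    "candidate_grid"
  )
})

test_that("the two methods separate well-separated cloud regimes consistently", {
  cfg <- synthetic_config(seed = 303, n_days = 12, cloud_model = "separated",
                          start_date = as.Date("2020-06-01"))
  sim <- simulate_station(cfg)
  sel <- select_cf_threshold(sim$uvi, sim$cf, sim$uvi_cs, cfg$station)
  expect_gte(sel$cf_threshold, 0.1)
  expect_lte(sel$cf_threshold, 0.5)
  expect_gte(sel$agreement, 0.9)
})
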