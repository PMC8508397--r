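test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 12, n_days = 2)
  a <- simulate_station(cfg)
  b <- simulate_station(cfg)
  expect_identical(a$uvi, b$uvi)
  expect_identical(a$cf, b$cf)
  expect_identical(a$labels, b$labels)

  other <- simulate_station(synthetic_config(seed = 13, n_days = 2))
  expect_false(identical(a$uvi$uvi, other$uvi$uvi))

  expect_error(synthetic_config(), "seed")
})

test_that("zero cloud noise reproduces the seasonal diurnal baseline exactly", {
  cfg <- synthetic_config(seed = 1, cf_noise_sd = 0)
  d_dry <- generate_cloud_day(cfg, as.Date("2020-07-01"))
  expect_equal(d_dry$cf$cf_total,
               pmin(pmax(erythemal:::cloud_baseline(0:1439) * 0.85, 0), 1))
  d_wet <- generate_cloud_day(cfg, as.Date("2020-01-01"))
  expect_equal(d_wet$cf$cf_total,
               pmin(pmax(erythemal:::cloud_baseline(0:1439) * 1.15, 0), 1))

  # thin deck present only from 08:00 local, components consistent
  lt <- erythemal:::local_minute_of_day(d_dry$cf$timestamp, cfg$station)
  expect_true(all(d_dry$cf$cf_thin[lt < 480] == 0))
  expect_true(all(abs(d_dry$cf$cf_thin[lt >= 480] -
                        pmin(0.15, d_dry$cf$cf_total[lt >= 480])) < 1e-12))
  expect_true(all(d_dry$cf$cf_thick + d_dry$cf$cf_thin <=
                    d_dry$cf$cf_total + 1e-12))
})

test_that("many seeded days reproduce the baseline cloud cycle on average", {
  cfg <- synthetic_config(seed = 55)
  date <- as.Date("2020-07-01")
  acc <- numeric(1440)
  n <- 400
  for (i in seq_len(n)) {
    acc <- acc + generate_cloud_day(cfg, date, seed = 1e6 + i)$cf$cf_total
  }
  target <- pmin(pmax(erythemal:::cloud_baseline(0:1439) * 0.85, 0), 1)
  expect_lt(max(abs(acc / n - target)), 0.02)
})

test_that("cloud modification spans the attenuation-enhancement envelope", {
  cfg <- quiet_config(seed = 3)
  st <- cfg$station
  date <- as.Date("2020-01-15")
  minutes <- erythemal:::day_minute_grid(st, date)

  # cloud-free: all-sky equals clear-sky exactly
  clear_cloud <- list(cf = cloud_series(minutes, rep(0, 1440)),
                      labels = NULL)
  d0 <- generate_uvi_day(cfg, date, cloud = clear_cloud)
  expect_equal(d0$uvi$uvi, d0$uvi_cs$uvi_cs)

  # full overcast at cmf_a = 0.75: a 75 % reduction everywhere
  thick_cloud <- list(cf = cloud_series(minutes, rep(1, 1440)), labels = NULL)
  d1 <- generate_uvi_day(cfg, date, cloud = thick_cloud)
  expect_equal(d1$uvi$uvi, 0.25 * d1$uvi_cs$uvi_cs)

  # with noise and enhancement on, output stays inside [0, 1.2 x clear-sky]
  noisy <- synthetic_config(seed = 9, p_enhance = 0.3, sensor_noise_sd = 0.05,
                            cloud_model = "separated")
  for (d in as.Date(c("2020-01-05", "2020-07-05"))) {
    day <- generate_uvi_day(noisy, d)
    expect_true(all(day$uvi$uvi >= 0))
    expect_true(all(day$uvi$uvi <= day$uvi_cs$uvi_cs * 1.2 + 1e-9))
    enh <- day$uvi$uvi > day$uvi_cs$uvi_cs
    expect_true(all(day$cmf[enh] <= 1.2))
  }

  # true labels follow the CF threshold rule
  sep <- generate_cloud_day(noisy, as.Date("2020-02-01"))
  expect_identical(sep$labels$label,
                   ifelse(sep$cf$cf_total < noisy$label_threshold,
                          "clear", "cloudy"))
})

test_that("hike records are altitude-adjusted subsamples of the station day", {
  cfg <- quiet_config(seed = 21)
  st <- cfg$station
  date <- as.Date("2020-01-12")
  day <- generate_uvi_day(cfg, date)
  ts <- erythemal:::day_minute_grid(st, date)[seq(300, 900, by = 10)]

  flat <- generate_hike(cfg, tibble::tibble(timestamp = ts,
                                            altitude_km = st$altitude_km))
  expect_equal(flat$uvi, day$uvi$uvi[match(ts, day$uvi$timestamp)])

  # Karthala summit versus sea level at clear noon: the altitude factor
  summit <- generate_hike(cfg, tibble::tibble(timestamp = ts,
                                              altitude_km = 2.36))
  ratio <- summit$uvi / flat$uvi
  f <- (1 + 0.06 * 2.36) / (1 + 0.06 * st$altitude_km)
  expect_equal(ratio[is.finite(ratio)],
               rep(f, sum(is.finite(ratio))), tolerance = 1e-9)

  expect_identical(generate_hike(cfg, tibble::tibble(timestamp = ts,
                                                     altitude_km = 1)),
                   generate_hike(cfg, tibble::tibble(timestamp = ts,
                                                     altitude_km = 1)))
})

test_that("estimate streams honour bias, sampling mode and determinism", {
  cfg <- quiet_config(seed = 33, n_days = 6, cloud_model = "separated")
  sim <- simulate_station(cfg)

  # satellite mode: one estimate per day, about an hour after solar noon
  sat <- generate_estimates(sim, cfg, bias = 1, noise_sd = 0, smooth_min = 0)
  expect_equal(nrow(sat), 6)
  noons <- local_solar_noon(cfg$station,
                            unique(erythemal:::local_date(sim$uvi$timestamp,
                                                          cfg$station)))
  expect_true(all(abs(as.numeric(sat$timestamp) - as.numeric(noons) - 3600) < 60))

  # unbiased, unsmoothed estimates equal the truth at the sampled instants
  idx <- erythemal:::nearest_match(sat$timestamp, sim$uvi$timestamp, 60)
  expect_equal(sat$uvi, sim$uvi$uvi[idx])

  # model mode: one estimate per forecast hour per day
  mod <- generate_estimates(sim, cfg, mode = "model", smooth_min = 0)
  expect_equal(nrow(mod), 6 * 4)

  # jittered coordinates stay inside the colocation gate
  expect_true(all(geosphere::distHaversine(
    cbind(mod$longitude, mod$latitude),
    c(cfg$station$longitude, cfg$station$latitude), r = 6371000) / 1000 < 10))

  expect_identical(generate_estimates(sim, cfg, bias = 1.1, noise_sd = 0.05),
                   generate_estimates(sim, cfg, bias = 1.1, noise_sd = 0.05))
})
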