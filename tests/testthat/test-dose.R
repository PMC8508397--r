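test_that("UVI converts to erythemal irradiance by definition", {
  expect_equal(uvi_to_erythemal_irradiance(0), 0)
  expect_equal(uvi_to_erythemal_irradiance(40), 1)
  expect_equal(uvi_to_erythemal_irradiance(20), 0.5)
  expect_error(uvi_to_erythemal_irradiance(-1), "non-negative")
})

test_that("per-window doses integrate irradiance in SED units", {
  st <- equator_station()
  day <- as.Date("2020-03-20")

  # a constant UVI of 20 gives 0.30 SED per one-minute window
  d20 <- sed_per_window(grid_series(st, day, rep(20, 1440)), station = st)
  expect_equal(unique(d20$sed), 0.3)
  expect_false(any(d20$partial))

  expect_equal(unique(sed_per_window(grid_series(st, day, rep(0, 1440)),
                                     station = st)$sed), 0)

  # 8 hours of constant UVI 10: 10/40 W m-2 * 28800 s / 100 J m-2 = 72 SED
  uvi8 <- c(rep(0, 480), rep(10, 480), rep(0, 480))
  d8 <- sed_per_window(grid_series(st, day, uvi8), station = st)
  expect_equal(sum(d8$sed), 72)

  expect_error(sed_per_window(grid_series(st, day, rep(20, 1440)),
                              window = 90), "multiple of 60")
})

test_that("daily dose totals are invariant to the window size", {
  st <- moroni_station()
  cfg <- quiet_config(seed = 5)
  day <- generate_uvi_day(cfg, as.Date("2020-02-10"))
  d60 <- sed_per_window(day$uvi, window = 60, station = st)
  d300 <- sed_per_window(day$uvi, window = 300, station = st)
  expect_lt(abs(sum(d60$sed) - sum(d300$sed)), 1e-6)
  expect_equal(nrow(d60), 1440)
  expect_equal(nrow(d300), 288)
})

test_that("cumulative dose equals brute-force fine-grained integration and resets daily", {
  st <- moroni_station()
  cfg <- quiet_config(seed = 6, n_days = 2, start_date = as.Date("2020-02-10"))
  sim <- simulate_station(cfg)
  doses <- cumulative_sed(sed_per_window(sim$uvi, station = st))

  # brute force: second-by-second prefix sums of the per-minute irradiance
  for (d in unique(doses$day)) {
    dd <- doses[doses$day == d, ]
    uvi_min <- sim$uvi$uvi[erythemal:::local_date(sim$uvi$timestamp, st) == d]
    per_sec <- rep(uvi_min / 40, each = 60) / 100      # SED per second
    brute <- cumsum(per_sec)[seq_len(1440) * 60]
    expect_lt(max(abs(dd$csed - brute)), 1e-9)
    expect_true(all(diff(dd$csed) >= -1e-12))
    expect_equal(dd$csed[1], dd$sed[1])  # reset at the day boundary
  }
})

test_that("gap policy interpolates short gaps and zeroes long ones", {
  st <- equator_station()
  day <- as.Date("2020-03-20")
  full <- grid_series(st, day, rep(20, 1440))

  short_gap <- full[-(601:605), ]   # 5-minute hole: bridged
  d_short <- sed_per_window(short_gap, station = st)
  expect_equal(sum(d_short$sed), sum(sed_per_window(full, station = st)$sed))
  expect_false(any(d_short$partial))

  long_gap <- full[-(601:660), ]    # 60-minute hole: zero dose, day partial
  d_long <- sed_per_window(long_gap, station = st)
  expect_true(all(d_long$partial))
  expect_lt(sum(d_long$sed), sum(d_short$sed))
})

test_that("phototype threshold crossings are ordered and handle edge thresholds", {
  st <- moroni_station()
  cfg <- quiet_config(seed = 7)
  day <- generate_uvi_day(cfg, as.Date("2020-01-15"),
                          cloud = list(cf = cloud_series(
                            daily_clearsky_profile(st, as.Date("2020-01-15"), 260)$timestamp,
                            rep(0, 1440)),
                            labels = NULL))
  doses <- cumulative_sed(sed_per_window(day$uvi, station = st))

  cross <- exceedance_time(doses)
  expect_true(all(cross$crossed))
  t_by_type <- setNames(cross$time, cross$phototype)
  expect_lt(as.numeric(t_by_type["I"]), as.numeric(t_by_type["VI"]))
  # monotone: a larger threshold never crosses earlier
  expect_true(all(diff(as.numeric(cross$time[order(cross$threshold_sed)])) >= 0))

  never <- exceedance_time(doses, tibble::tibble(phototype = "X",
                                                 threshold_sed = 1e6))
  expect_false(never$crossed)

  zero <- exceedance_time(doses, tibble::tibble(phototype = "Z",
                                                threshold_sed = 0))
  first_nonzero <- doses$window_start[which(doses$csed > 0)[1]]
  expect_identical(zero$time, first_nonzero)

  expect_error(fitzpatrick_thresholds(I = 5, VI = 2), "non-decreasing")
})

test_that("WHO categories use inclusive lower bounds and sum to one", {
  expect_identical(as.character(who_category(c(0, 2.9, 3, 5.9, 6, 8, 11, 25))),
                   c("low", "low", "moderate", "moderate", "high",
                     "very_high", "extreme", "extreme"))
  expect_error(who_category(-2), "non-negative")

  f <- category_frequencies(c(2, 5, 7, 9, 12))
  expect_equal(f$frequency, rep(0.2, 5))
  expect_equal(sum(f$frequency), 1)

  f12 <- category_frequencies(rep(12, 10))
  expect_equal(f12$frequency[f12$category == "extreme"], 1)
  expect_error(category_frequencies(numeric()), "no UVI values")
})
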