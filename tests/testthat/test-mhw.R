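test_that("climatology degenerates correctly on a constant series", {
  clim <- build_climatology(flat_series(10), c(2000, 2012))
  expect_equal(nrow(clim), 366)
  expect_true(all(clim$clim_mean == 10))
  expect_true(all(clim$threshold == 10))
})

test_that("climatology reproduces a pure sinusoid within smoothing bias", {
  sc <- temperature_scenario("1990-01-01", "2009-12-31", mean_annual = 8,
                             seasonal_amplitude = 3, phase_day = 210,
                             ar1_phi = 0, noise_sd = 0)
  ts <- generate_temperature(sc)
  clim <- build_climatology(ts, c(1990, 2009))
  doy <- 1:365
  oracle <- 8 + 3 * cos(2 * pi * (doy - 210) / 365.25)
  got <- clim$clim_mean[clim$doy != 60][doy]
  expect_lt(max(abs(got - oracle)), 0.05)
})

test_that("day-of-year pooling is circular at the year boundary", {
  # temp = civil day-of-year slot; no smoothing isolates the pooling window
  dates <- seq(as.Date("2001-01-01"), as.Date("2010-12-31"), by = "day")
  ref <- format(seq(as.Date("2001-01-01"), as.Date("2001-12-31"), "day"),
                "%m-%d")
  slot <- match(format(dates, "%m-%d"), ref)
  slot[is.na(slot)] <- 59  # Feb 29 pools with Feb 28
  ts <- data.frame(date = dates, temp_c = as.numeric(slot))
  clim <- build_climatology(ts, c(2001, 2010), smooth_width = 1)
  # day 1 pools civil days 361..365 and 1..6
  expect_equal(clim$clim_mean[1], mean(c(361:365, 1:6)), tolerance = 1e-9)
})

test_that("climatology is invariant to permuting baseline years", {
  sc <- temperature_scenario("2001-01-01", "2010-12-31", seed = 4)
  ts <- generate_temperature(sc)
  yrs <- as.integer(format(ts$date, "%Y"))
  perm <- ts  # 2003 and 2007 are both non-leap: same length vectors
  perm$temp_c[yrs == 2003] <- ts$temp_c[yrs == 2007]
  perm$temp_c[yrs == 2007] <- ts$temp_c[yrs == 2003]
  expect_equal(build_climatology(perm, c(2001, 2010))$clim_mean,
               build_climatology(ts, c(2001, 2010))$clim_mean,
               tolerance = 1e-9)
})

test_that("event detection: degenerate, worked and gap-merge cases", {
  base <- flat_series(10, "2000-01-01", "2012-12-31")
  clim <- build_climatology(base, c(2000, 2010))
  # constant at climatology: zero events (not strictly above threshold)
  expect_equal(nrow(detect_events(base, clim)), 0)

  # one +5 block of 10 days: duration 10, cumulative intensity 50
  ts <- base
  block <- ts$date >= as.Date("2011-06-01") & ts$date <= as.Date("2011-06-10")
  ts$temp_c[block] <- 15
  # flat climatology: detection works but category is degenerate (NA)
  expect_warning(ev <- detect_events(ts, clim), "degenerate")
  expect_true(is.na(ev$category))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_days, 10L)
  expect_equal(ev$cum_intensity_c_days, 50)
  expect_equal(ev$max_intensity_c, 5)
  expect_equal(ev$start, as.Date("2011-06-01"))

  # two 5-day runs separated by a 2-day dip merge into a 12-day event
  ts2 <- base
  run1 <- ts2$date >= as.Date("2011-06-01") & ts2$date <= as.Date("2011-06-05")
  run2 <- ts2$date >= as.Date("2011-06-08") & ts2$date <= as.Date("2011-06-12")
  ts2$temp_c[run1 | run2] <- 13
  ev2 <- suppressWarnings(detect_events(ts2, clim))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_days, 12L)
  # gap days below climatology are excluded from cumulative intensity
  expect_equal(ev2$cum_intensity_c_days, 30)

  # sub-threshold-duration runs are dropped
  ts3 <- base
  short <- ts3$date >= as.Date("2011-06-01") & ts3$date <= as.Date("2011-06-04")
  ts3$temp_c[short] <- 13
  expect_equal(nrow(detect_events(ts3, clim)), 0)
})

test_that("categories follow integer multiples of the threshold gap", {
  # constant 10 degC baseline with noise-free spread: build a climatology
  # whose threshold-mean gap is exactly 1 by injecting a known quantile
  dates <- seq(as.Date("2000-01-01"), as.Date("2010-12-31"), by = "day")
  set.seed(1)
  # alternate 9 and 11 around mean 10: p90 pools to 11, mean 10 -> gap 1
  ts <- data.frame(date = dates,
                   temp_c = rep(c(9, 11), length.out = length(dates)))
  clim <- build_climatology(ts, c(2000, 2010))
  gap <- clim$threshold[150] - clim$clim_mean[150]
  expect_equal(gap, 1, tolerance = 0.1)
  ref366 <- format(seq(as.Date("2000-01-01"), as.Date("2000-12-31"), "day"),
                   "%m-%d")
  probe <- function(peak) {
    t2 <- flat_series(10, "2000-01-01", "2012-12-31")
    blk <- which(t2$date >= as.Date("2011-06-01") &
                   t2$date <= as.Date("2011-06-10"))
    idx <- match(format(t2$date[blk], "%m-%d"), ref366)
    # anomaly is exactly peak x the local threshold gap on every block day
    t2$temp_c[blk] <- clim$clim_mean[idx] +
      peak * (clim$threshold[idx] - clim$clim_mean[idx])
    detect_events(t2, clim)$category
  }
  expect_equal(probe(1.5), "Moderate")
  expect_equal(probe(2.5), "Strong")
  expect_equal(probe(3.5), "Severe")
  expect_equal(probe(4.2), "Extreme")
  # the categorisation operation itself rejects a degenerate gap
  expect_equal(categorize(1.5, 1), "Moderate")
  expect_equal(categorize(2.5, 1), "Strong")
  expect_equal(categorize(4.2, 1), "Extreme")
  expect_error(categorize(2, 0), "degenerate")
})

test_that("detection is invariant to a uniform temperature shift", {
  sc <- temperature_scenario("1995-01-01", "2012-12-31", seed = 8,
                             anomalies = data.frame(
                               start_date = "2011-06-01",
                               duration_days = 30, intensity_c = 3))
  ts <- generate_temperature(sc)
  shifted <- transform(ts, temp_c = temp_c + 4)
  ev <- detect_events(ts, build_climatology(ts, c(1995, 2009)))
  ev_s <- detect_events(shifted, build_climatology(shifted, c(1995, 2009)))
  expect_equal(ev$start, ev_s$start)
  expect_equal(ev$cum_intensity_c_days, ev_s$cum_intensity_c_days,
               tolerance = 1e-9)
})

test_that("years classify from synthetic anomalies and the fixture validates", {
  sc <- temperature_scenario(
    "2000-01-01", "2012-12-31", seed = 13,
    anomalies = data.frame(
      start_date = c("2008-04-01", "2009-04-01", "2010-04-01"),
      duration_days = 200, intensity_c = 3))
  ts <- generate_temperature(sc)
  # short baseline is deliberate here (anomalies start in 2008)
  expect_warning(clim <- build_climatology(ts, c(2000, 2007)),
                 "fewer than 10 years")
  ev <- detect_events(ts, clim)
  yc <- classify_years(ev, 2000:2012)
  expect_equal(yc$class[yc$year %in% 2008:2010], rep("Heatwave", 3))
  expect_equal(yc$class[yc$year == 2012], "Between")
  expect_true(all(yc$class[yc$year < 2008] == "Before"))

  # zero events everywhere: all Before
  flat_clim <- build_climatology(flat_series(10), c(2000, 2010))
  yc0 <- classify_years(detect_events(flat_series(10), flat_clim),
                        2000:2005)
  expect_true(all(yc0$class == "Before"))

  # the published year binning ships as a fixture and loads intact
  ref <- reference_year_classes()
  expect_equal(ref$class[ref$year %in% c(2014:2016, 2019)],
               rep("Heatwave", 4))
  expect_equal(ref$class[ref$year %in% 2017:2018], rep("Between", 2))
  expect_equal(ref$class[ref$year %in% 2006:2013], rep("Before", 8))
})
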