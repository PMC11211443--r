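test_that("temperature generator: degenerate, anomaly and determinism contracts", {
  # flat series
  sc <- temperature_scenario("2000-01-01", "2001-12-31", mean_annual = 9,
                             seasonal_amplitude = 0, ar1_phi = 0,
                             noise_sd = 0)
  ts <- generate_temperature(sc)
  expect_equal(nrow(ts), 731)
  expect_true(all(ts$temp_c == 9))

  # one +5 block of 10 days on the flat series
  sc2 <- temperature_scenario("2000-01-01", "2001-12-31", mean_annual = 9,
                              seasonal_amplitude = 0, ar1_phi = 0,
                              noise_sd = 0,
                              anomalies = data.frame(
                                start_date = "2000-06-01",
                                duration_days = 10, intensity_c = 5))
  ts2 <- generate_temperature(sc2)
  elevated <- ts2$temp_c > 9
  expect_equal(sum(elevated), 10)
  expect_true(all(ts2$temp_c[elevated] == 14))
  expect_equal(ts2$date[elevated][1], as.Date("2000-06-01"))

  # determinism under fixed seed, with noise on
  sc3 <- temperature_scenario("2000-01-01", "2005-12-31", seed = 42)
  expect_identical(generate_temperature(sc3), generate_temperature(sc3))

  # invalid scenarios rejected
  expect_error(temperature_scenario("2001-01-01", "2000-01-01"), "before")
  expect_error(temperature_scenario("2000-01-01", "2001-01-01",
                                    ar1_phi = 1), "ar1_phi")
})

test_that("overlapping anomaly blocks add their intensities", {
  sc <- temperature_scenario("2000-01-01", "2000-12-31", mean_annual = 8,
                             seasonal_amplitude = 0, ar1_phi = 0,
                             noise_sd = 0,
                             anomalies = data.frame(
                               start_date = c("2000-06-01", "2000-06-05"),
                               duration_days = c(10, 10),
                               intensity_c = c(2, 3)))
  ts <- generate_temperature(sc)
  overlap <- ts$date >= as.Date("2000-06-05") & ts$date <= as.Date("2000-06-10")
  expect_true(all(ts$temp_c[overlap] == 13))
})

test_that("degenerate cohort grows at exactly e^intercept per day", {
  tt <- flat_series(10, "2009-01-01", "2010-12-31")
  sampling <- data.frame(year = 2010, month = 7, class = "Before",
                         n_fish = 3)
  sc <- cohort_scenario(sampling, settlement_length_sd = 0,
                        growth_coefficients = list(
                          intercept = -4, size = 0, temperature = 0,
                          class_between = 0, class_during = 0),
                        fish_intercept_sd = 0, day_slope_sd = 0,
                        resid_sd = 0, resid_ar1_phi = 0,
                        allometry = list(ln_intercept = -11.83,
                                         ln_slope = 3.07,
                                         lognormal_sd = 0),
                        hsi_sd = 0, seed = 5)
  ch <- generate_cohort(sc, tt)
  # capture length = 40 * (1 + e^-4)^21 for every fish
  expect_equal(ch$fish$sl_mm, rep(40 * (1 + exp(-4))^21, 3),
               tolerance = 1e-12)
  # allometry with zero noise falls exactly on the configured line
  expect_equal(log(ch$fish$mass_g), -11.83 + 3.07 * log(ch$fish$sl_mm),
               tolerance = 1e-12)
})

test_that("generated otolith tracks round-trip through back-calculation", {
  tt <- flat_series(10, "2009-01-01", "2010-12-31")
  sampling <- data.frame(year = 2010, month = c(7, 8),
                         class = c("Before", "Heatwave"), n_fish = 4)
  sc <- cohort_scenario(sampling, seed = 11)
  ch <- generate_cohort(sc, tt)
  for (id in unique(ch$otolith$fish_id)) {
    tr <- ch$otolith[ch$otolith$fish_id == id, ]
    tr <- tr[order(tr$increment_index), ]
    L <- back_calculate_lengths(tr$radius_um, tr$radius_at_capture_um[1],
                                ch$fish$sl_mm[ch$fish$fish_id == id])
    # capture length recovered exactly; daily lengths to 1e-9 mm
    expect_equal(L[length(L)], ch$fish$sl_mm[ch$fish$fish_id == id])
    g <- relative_growth(L)
    expect_true(all(is.finite(g$rel_growth)))
  }
  # byte-identical regeneration under the same scenario + seed
  expect_identical(generate_cohort(sc, tt), ch)
})

test_that("apply_survival implements its three modes exactly", {
  fish <- data.frame(fish_id = letters[1:4], sl_mm = c(60, 70, 80, 90))
  expect_identical(apply_survival(fish, "none"), fish)
  kept <- apply_survival(fish, "quantile_truncation", q_survive = 0.5)
  expect_setequal(kept$sl_mm, c(80, 90))
  # ceiling rule: q = 0.6 of 4 -> 3 fish
  expect_equal(nrow(apply_survival(fish, "quantile_truncation",
                                   q_survive = 0.6)), 3)
  expect_error(apply_survival(fish, "quantile_truncation", q_survive = 0),
               "q_survive")
  # logistic limit: step function at l50
  two <- data.frame(fish_id = c("a", "b"), sl_mm = c(60, 90))
  kept2 <- apply_survival(two, "logistic_by_size", l50 = 75,
                          slope = 1e6, seed = 3)
  expect_identical(kept2$sl_mm, 90)
})

test_that("diet generator honours empty probability and profiles", {
  fish <- data.frame(fish_id = sprintf("F%03d", 1:400), class = "Before",
                     month = 7L, mass_g = 2)
  prof1 <- diet_profile(data.frame(class = "Before", month = 7L,
                                   prey_taxon = "mysid", prob = 1,
                                   weight_mean_mg = 5, weight_sd_mg = 2,
                                   empty_probability = 1, items_mean = 6))
  st <- generate_diets(fish, prof1, seed = 2)
  expect_true(all(is.na(st$prey_taxon)))
  expect_true(all(st$count == 0))

  # single-taxon profile: every non-empty stomach contains only that taxon
  prof2 <- diet_profile(transform(prof1, empty_probability = 0.1))
  st2 <- generate_diets(fish, prof2, seed = 2)
  expect_true(all(is.na(st2$prey_taxon) | st2$prey_taxon == "mysid"))

  # law of large numbers: empirical empty fraction within binomial 99% CI
  p_hat <- mean(tapply(is.na(st2$prey_taxon), st2$fish_id, any))
  ci <- 0.1 + c(-1, 1) * 2.58 * sqrt(0.1 * 0.9 / 400)
  expect_gt(p_hat, ci[1]); expect_lt(p_hat, ci[2])

  # missing profile for a present stratum rejected
  fish$class <- "Heatwave"
  expect_error(generate_diets(fish, prof2, seed = 2), "missing")
})

test_that("zero-variance cohorts make July->August growth exactly deterministic", {
  tt <- flat_series(10, "2009-01-01", "2010-12-31")
  sampling <- data.frame(year = 2010, month = c(7, 8), class = "Before",
                         n_fish = 5,
                         start_length_mean = c(40, 55),
                         start_length_sd = 0)
  sc <- cohort_scenario(sampling, settlement_length_sd = 0,
                        growth_coefficients = list(
                          intercept = -4.5, size = 0, temperature = 0,
                          class_between = 0, class_during = 0),
                        fish_intercept_sd = 0, day_slope_sd = 0,
                        resid_sd = 0, resid_ar1_phi = 0, seed = 9)
  ch <- generate_cohort(sc, tt)
  jul <- ch$fish[ch$fish$month == 7, ]
  aug <- ch$fish[ch$fish$month == 8, ]
  rate <- 1 + exp(-4.5)
  expect_equal(mean(jul$sl_mm), 40 * rate^21, tolerance = 1e-12)
  expect_equal(mean(aug$sl_mm), 55 * rate^21, tolerance = 1e-12)
})
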