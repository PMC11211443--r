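test_that("August size projection compounds July growth", {
  jul <- data.frame(fish_id = c("a", "b"), year = 2014,
                    class = "Heatwave", sl_mm = c(50, 60))
  g <- data.frame(year = 2014, mean_growth = 0.01)
  pred <- predict_august_sizes(jul, g, days = 40)
  expect_equal(pred$predicted_aug_mm, c(50, 60) * 1.01^40,
               tolerance = 1e-12)
  # zero growth: predictions equal July sizes
  pred0 <- predict_august_sizes(jul, transform(g, mean_growth = 0))
  expect_equal(pred0$predicted_aug_mm, jul$sl_mm)
  # doubling the interval doubles the log-scale increment exactly
  p80 <- predict_august_sizes(jul, g, days = 80)
  expect_equal(log(p80$predicted_aug_mm / jul$sl_mm),
               2 * log(pred$predicted_aug_mm / jul$sl_mm),
               tolerance = 1e-12)
  # multiplicative projection commutes with unit rescaling
  pred_cm <- predict_august_sizes(transform(jul, sl_mm = sl_mm / 10), g,
                                  days = 40)
  expect_equal(pred_cm$predicted_aug_mm * 10, pred$predicted_aug_mm,
               tolerance = 1e-12)
  # years with no growth summary are dropped with a warning
  jul2 <- rbind(jul, data.frame(fish_id = "c", year = 2015,
                                class = "Heatwave", sl_mm = 70))
  expect_warning(pm <- predict_august_sizes(jul2, g), "2015")
  expect_equal(nrow(pm), 2)
})

test_that("predicted-observed comparison reports per-year then class gaps", {
  pred <- data.frame(year = rep(c(2014, 2015), each = 20),
                     class = "Heatwave",
                     predicted_aug_mm = rep(c(50, 60), each = 20))
  obs <- data.frame(year = rep(c(2014, 2015), each = 20),
                    class = "Heatwave", sl_mm = rep(c(60, 78), each = 20))
  res <- compare_predicted_observed(pred, obs)
  expect_equal(res$by_year$pct_gap, c(20, 30))
  expect_equal(res$by_class$mean_gap_pct, 25)
  expect_equal(res$by_class$se_gap_pct, 5)
  # identical distributions: zero gap
  same <- compare_predicted_observed(
    transform(pred, predicted_aug_mm = 55),
    transform(obs, sl_mm = 55))
  expect_equal(same$by_class$mean_gap_pct, 0)
  # the printed single-year arithmetic: 73.81 -> 92.66 is +25.5%
  expect_equal(round(100 * (92.66 - 73.81) / 73.81, 1), 25.5)
})

test_that("top-quantile mean matches enumeration and stays monotone", {
  x <- c(70, 80, 90, 100)
  # exact enumeration at multiples of 1/n
  for (k in 1:4)
    expect_equal(top_quantile_mean(x, k / 4), mean(sort(x, TRUE)[1:k]))
  # fractional q interpolates the boundary observation
  expect_equal(top_quantile_mean(x, 0.15), 100)
  # monotone non-increasing on random sets (property, seeded)
  set.seed(14)
  for (i in 1:5) {
    v <- rnorm(23, 80, 10)
    qs <- seq(0.05, 1, by = 0.05)
    tm <- vapply(qs, function(q) top_quantile_mean(v, q), numeric(1))
    expect_true(all(diff(tm) <= 1e-9))
  }
})

test_that("survival quantile search matches hand enumeration", {
  x <- c(70, 80, 90, 100)
  # observed equal to the overall mean: everything survived
  expect_equal(survival_quantile_search(x, 85)$q_star, 1)
  # observed 95 = mean of the top half
  expect_equal(survival_quantile_search(x, 95)$q_star, 0.5)
  # observed equal to the maximum: only the top quarter
  expect_equal(survival_quantile_search(x, 100)$q_star, 0.25)
  # observed above the maximum: undefined
  expect_true(is.na(survival_quantile_search(x, 101)$q_star))
  # CI coverage reporting
  res <- survival_quantile_search(x, 95, observed_ci = c(94, 96))
  expect_true(res$curve$within_ci[res$curve$q == 0.5])
})

test_that("normal top-q closed form matches simulation within 3 MC SEs", {
  set.seed(31)
  mu <- 80.6; s <- 8; n <- 10000
  draws <- rnorm(n, mu, s)
  for (q in c(0.15, 0.25, 0.5)) {
    oracle <- normal_top_q_mean(mu, s, q)
    got <- top_quantile_mean(draws, q)
    # MC SE of a tail mean: tail sd / sqrt(qN), bounded by s/sqrt(qN)
    expect_lt(abs(got - oracle), 3 * s / sqrt(q * n))
  }
})

test_that("simulated populations reproduce the survival-quantile analysis", {
  sim <- simulate_populations(pred_mean = 80.6, pred_sd = 9,
                              obs_mean = 93.5, obs_sd = 8,
                              n_pred = 84, n_obs = 53, seed = 5)
  expect_equal(length(sim$pred_population), 10000)
  expect_true(sim$q_star > 0 && sim$q_star <= 1)
  # reproducible under the same seed
  sim2 <- simulate_populations(80.6, 9, 93.5, 8, 84, 53, seed = 5)
  expect_identical(sim$q_star, sim2$q_star)
  # doubling N leaves q* unchanged within Monte-Carlo error
  sim_big <- simulate_populations(80.6, 9, 93.5, 8, 84, 53,
                                  n_pop = 20000L, seed = 5)
  expect_lt(abs(sim_big$q_star - sim$q_star), 0.1)
  expect_error(simulate_populations(80, 0, 93, 8, 10, 10), "positive")
})
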