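#' Describe a synthetic fish cohort
#'
#' Houses the generating truth for the growth, otolith, allometry and
#' condition stages. Daily log relative growth follows the nursery
#' growth model: fixed effects (on standardized size and temperature,
#' plus heatwave-class offsets), a per-fish random intercept, a random
#' day-of-life slope, and stationary AR(1) residuals. Lengths compound
#' multiplicatively (`L_t = L_{t-1} * (1 + g_t)`, g in mm/mm/day);
#' otolith radii are constructed by exactly inverting the Biological
#' Intercept model so back-calculation round-trips; mass follows the
#' log-linear allometry with lognormal noise; liver mass follows the
#' HSI distribution.
#'
#' @param sampling data.frame `year`, `month`, `class`, `n_fish`,
#'   optionally `start_length_mean`, `start_length_sd` overrides.
#' @param settlement_length_mean,settlement_length_sd length (mm) at
#'   the start of the growth window when not overridden per stratum.
#' @param growth_coefficients named list: `intercept`, `size`,
#'   `temperature`, `class_between`, `class_during`, on the log
#'   relative-growth scale with standardized covariates.
#' @param size_center,size_scale,temp_center,temp_scale the fixed
#'   standardization constants the generator applies to length (mm) and
#'   temperature (deg C) covariates.
#' @param fish_intercept_sd,day_slope_sd random-effect SDs (log units).
#' @param resid_sd,resid_ar1_phi residual marginal SD and AR(1)
#'   coefficient.
#' @param allometry named list `ln_intercept`, `ln_slope`,
#'   `lognormal_sd` for ln(mass g) on ln(SL mm).
#' @param hsi_mean,hsi_sd hepatosomatic index distribution, percent.
#' @param biological_intercept list `L0` (mm), `O0` (um).
#' @param otolith_relation list `intercept`, `slope`, `sd`: capture
#'   radius (um) as a linear function of capture length (mm) plus
#'   Gaussian noise (the radius-length noise structure is deliberately
#'   configuration, not an asserted field value).
#' @param window growth window length, days (default 21).
#' @param capture_day named vector month -> day-of-month of capture.
#' @param inter_sampling_days days between July and August sampling.
#' @param n_sites,hauls_per_site labels for site/haul assignment.
#' @param seed integer seed.
#' @return object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(sampling,
                            settlement_length_mean = 40,
                            settlement_length_sd = 3,
                            growth_coefficients = list(
                              intercept = -4.43, size = -0.12,
                              temperature = -0.11, class_between = 0.07,
                              class_during = 0.15),
                            size_center = 60, size_scale = 15,
                            temp_center = 10, temp_scale = 1.5,
                            fish_intercept_sd = 0.25,
                            day_slope_sd = 0.01,
                            resid_sd = 0.20, resid_ar1_phi = 0.3,
                            allometry = list(ln_intercept = -11.83,
                                             ln_slope = 3.07,
                                             lognormal_sd = 0.22),
                            hsi_mean = 2.5, hsi_sd = 0.6,
                            biological_intercept = list(L0 = 3.9, O0 = 8.3),
                            otolith_relation = list(intercept = 50,
                                                    slope = 9, sd = 0),
                            window = 21L,
                            capture_day = c("7" = 15L, "8" = 25L),
                            inter_sampling_days = 40L,
                            n_sites = 8L, hauls_per_site = 1L,
                            seed = 1L) {
  sampling <- as.data.frame(sampling)
  stopifnot(all(c("year", "month", "class", "n_fish") %in% names(sampling)),
            all(sampling$n_fish >= 0))
  stopifnot(settlement_length_sd >= 0, fish_intercept_sd >= 0,
            day_slope_sd >= 0, resid_sd >= 0,
            resid_ar1_phi >= 0, resid_ar1_phi < 1,
            biological_intercept$L0 > 0, biological_intercept$O0 > 0)
  structure(as.list(environment()), class = "cohort_scenario")
}

#' Generate fish and otolith tables from a cohort scenario
#'
#' @param scenario a [cohort_scenario()].
#' @param temps daily temperature data.frame `date`, `temp_c` covering
#'   each fish's growth window.
#' @return list of two data.frames: `fish` (`fish_id`, `year`, `month`,
#'   `class`, `site`, `haul`, `sl_mm`, `mass_g`, `liver_g`) and
#'   `otolith` (`fish_id`, `increment_index` 0..window, `radius_um`,
#'   `radius_at_capture_um`).
#' @export
generate_cohort <- function(scenario, temps) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  temps <- validate_temperature_series(temps)
  sc <- scenario
  b <- sc$growth_coefficients
  W <- sc$window
  withr_seed(derive_seed(sc$seed, "cohort"), {
    fish_rows <- list(); oto_rows <- list()
    fid <- 0L
    for (r in seq_len(nrow(sc$sampling))) {
      st <- sc$sampling[r, ]
      if (st$n_fish == 0) next
      cap_date <- as.Date(sprintf("%d-%02d-%02d", st$year, st$month,
                                  sc$capture_day[[as.character(st$month)]]))
      win_dates <- seq(cap_date - W, cap_date, by = "day")
      ti <- match(win_dates, temps$date)
      if (anyNA(ti))
        stop("temperature series does not cover ", st$year, "-", st$month,
             " growth window")
      tw <- temps$temp_c[ti]
      mu0 <- if (!is.null(st$start_length_mean) &&
                 !is.na(st$start_length_mean)) st$start_length_mean
      else sc$settlement_length_mean
      sd0 <- if (!is.null(st$start_length_sd) &&
                 !is.na(st$start_length_sd)) st$start_length_sd
      else sc$settlement_length_sd
      cls_eff <- switch(as.character(st$class),
                        Before = 0,
                        Between = b$class_between,
                        Heatwave = b$class_during,
                        During = b$class_during,
                        stop("unknown heatwave class: ", st$class))
      for (k in seq_len(st$n_fish)) {
        fid <- fid + 1L
        L <- numeric(W + 1)
        L[1] <- max(stats::rnorm(1, mu0, sd0), 5)
        b0 <- stats::rnorm(1, 0, sc$fish_intercept_sd)
        b1 <- stats::rnorm(1, 0, sc$day_slope_sd)
        e <- ar1_noise(W, sc$resid_ar1_phi, sc$resid_sd)
        for (t in seq_len(W)) {
          size_z <- (L[t] - sc$size_center) / sc$size_scale
          temp_z <- (tw[t] - sc$temp_center) / sc$temp_scale
          lg <- b$intercept + b$size * size_z + b$temperature * temp_z +
            cls_eff + b0 + b1 * (t - (W + 1) / 2) + e[t]
          L[t + 1] <- L[t] * (1 + exp(lg))
        }
        if (any(!is.finite(L)) || any(L <= 0))
          stop("implausible scenario: non-positive simulated length")
        Lc <- L[W + 1]
        Oc <- sc$otolith_relation$intercept +
          sc$otolith_relation$slope * Lc +
          stats::rnorm(1, 0, sc$otolith_relation$sd)
        bi <- sc$biological_intercept
        if (Oc <= bi$O0)
          stop("implausible scenario: capture radius below O0")
        radii <- Oc + (L - Lc) * (Oc - bi$O0) / (Lc - bi$L0)
        mass <- exp(sc$allometry$ln_intercept +
                      sc$allometry$ln_slope * log(Lc) +
                      stats::rnorm(1, 0, sc$allometry$lognormal_sd))
        hsi_val <- min(max(stats::rnorm(1, sc$hsi_mean, sc$hsi_sd), 0.05),
                       50)
        site <- ((fid - 1L) %% sc$n_sites) + 1L
        haul <- ((fid - 1L) %/% sc$n_sites) %% sc$hauls_per_site + 1L
        fish_rows[[fid]] <- data.frame(
          fish_id = sprintf("F%05d", fid), year = st$year,
          month = st$month, class = as.character(st$class),
          site = site, haul = haul, sl_mm = Lc, mass_g = mass,
          liver_g = hsi_val / 100 * mass)
        oto_rows[[fid]] <- data.frame(
          fish_id = sprintf("F%05d", fid), increment_index = 0:W,
          radius_um = radii, radius_at_capture_um = Oc)
      }
    }
  })
  list(fish = do.call(rbind, fish_rows),
       otolith = do.call(rbind, oto_rows))
}

#' Size-selective survival operator
#'
#' Applies one of three survival modes to a fish table: `none`
#' (identity), `quantile_truncation` (exactly the largest
#' `ceiling(q_survive * n)` fish by length are retained), or
#' `logistic_by_size` (independent Bernoulli survival with probability
#' `plogis(slope * (length - l50))`, seeded).
#'
#' @param fish fish data.frame with `sl_mm`.
#' @param mode `"none"`, `"quantile_truncation"` or
#'   `"logistic_by_size"`.
#' @param q_survive proportion retained under truncation, in `(0, 1]`.
#' @param l50 length at 50% survival, mm (logistic mode).
#' @param slope logistic slope, per mm.
#' @param seed integer seed (logistic mode).
#' @return the surviving subset of `fish`.
#' @export
apply_survival <- function(fish, mode = c("none", "quantile_truncation",
                                          "logistic_by_size"),
                           q_survive = 1, l50 = NULL, slope = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  fish <- as.data.frame(fish)
  if (nrow(fish) == 0) stop("fish table is empty")
  switch(mode,
         none = fish,
         quantile_truncation = {
           if (q_survive <= 0 || q_survive > 1)
             stop("q_survive must be in (0, 1]")
           k <- ceiling(q_survive * nrow(fish))
           keep <- order(fish$sl_mm, decreasing = TRUE)[seq_len(k)]
           fish[sort(keep), , drop = FALSE]
         },
         logistic_by_size = {
           stopifnot(!is.null(l50), !is.null(slope))
           p <- stats::plogis(slope * (fish$sl_mm - l50))
           keep <- withr_seed(derive_seed(seed, "survival"),
                              stats::runif(nrow(fish)) < p)
           fish[keep, , drop = FALSE]
         })
}

#' Simulate growth observations with an exogenous design
#'
#' Direct simulator for parameter-recovery experiments on the nursery
#' growth mixed model: standardized size (constant per fish) and
#' temperature (between- plus within-fish components, unit marginal
#' variance) covariates, class labels, and a response built from the
#' supplied fixed effects plus a per-fish random intercept, a random
#' day-of-life slope, and stationary AR(1) residuals. Unlike
#' [generate_cohort()], covariates here do not feed back on growth, so
#' fitting the same model is a clean recovery experiment.
#'
#' @param n_fish number of fish.
#' @param n_inc increments per fish (default 21).
#' @param beta named coefficients: `intercept`, `size`, `temperature`,
#'   `class_between`, `class_during`.
#' @param class_probs sampling probabilities for classes
#'   Before/Between/During.
#' @param sd_intercept,sd_slope,sd_resid,ar1_phi variance components.
#' @param temp_between_prop share of unit temperature variance that is
#'   between fish.
#' @param seed integer seed.
#' @return data.frame `fish_id` (factor), `increment_index`, `inc_c`
#'   (centered on the window midpoint), `size_z`, `temp_z`, `class`
#'   (factor, reference Before), `log_growth`.
#' @export
simulate_growth_observations <- function(n_fish, n_inc = 21L,
                                         beta = list(
                                           intercept = -4.43, size = -0.12,
                                           temperature = -0.11,
                                           class_between = 0.07,
                                           class_during = 0.15),
                                         class_probs = c(Before = 0.4,
                                                         Between = 0.25,
                                                         During = 0.35),
                                         sd_intercept = 0.25,
                                         sd_slope = 0.01,
                                         sd_resid = 0.20, ar1_phi = 0.3,
                                         temp_between_prop = 0.5,
                                         seed = 1L) {
  withr_seed(seed, {
    cls <- factor(sample(names(class_probs), n_fish, replace = TRUE,
                         prob = class_probs),
                  levels = c("Before", "Between", "During"))
    size_f <- stats::rnorm(n_fish)
    temp_f <- stats::rnorm(n_fish, 0, sqrt(temp_between_prop))
    b0 <- stats::rnorm(n_fish, 0, sd_intercept)
    b1 <- stats::rnorm(n_fish, 0, sd_slope)
    mid <- (n_inc + 1) / 2
    rows <- lapply(seq_len(n_fish), function(i) {
      inc <- seq_len(n_inc)
      temp_z <- temp_f[i] + stats::rnorm(n_inc, 0,
                                         sqrt(1 - temp_between_prop))
      e <- ar1_noise(n_inc, ar1_phi, sd_resid)
      eff <- switch(as.character(cls[i]), Before = 0,
                    Between = beta$class_between,
                    During = beta$class_during)
      y <- beta$intercept + beta$size * size_f[i] +
        beta$temperature * temp_z + eff + b0[i] + b1[i] * (inc - mid) + e
      data.frame(fish_id = i, increment_index = inc, inc_c = inc - mid,
                 size_z = size_f[i], temp_z = temp_z, class = cls[i],
                 log_growth = y)
    })
    out <- do.call(rbind, rows)
    out$fish_id <- factor(out$fish_id)
    out
  })
}
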