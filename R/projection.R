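#' Project July fish to expected August sizes
#'
#' Each July fish is grown forward from its size at capture for the
#' inter-sampling interval using its year's mean July relative growth
#' rate. Default is daily multiplicative compounding
#' `L_pred = L_capture * (1 + g_bar)^days`, the dimensionally
#' self-consistent reading of a mm/mm/day rate; the additive
#' interpretation `L_pred = L_capture + days * g_bar * mean(L)` is
#' available for comparison.
#'
#' @param july_fish data.frame with `fish_id`, `year`, `sl_mm`.
#' @param growth_by_year data.frame `year`, `mean_growth` (mean July
#'   relative growth, mm/mm/day).
#' @param days inter-sampling interval: single number or data.frame
#'   `year`, `days` (default 40).
#' @param mode `"multiplicative"` or `"additive"`.
#' @return `july_fish` with added `predicted_aug_mm`; years missing a
#'   growth summary are dropped with a warning.
#' @export
predict_august_sizes <- function(july_fish, growth_by_year, days = 40,
                                 mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  july_fish <- as.data.frame(july_fish)
  stopifnot(all(c("year", "sl_mm") %in% names(july_fish)),
            all(c("year", "mean_growth") %in% names(growth_by_year)))
  if (is.data.frame(days)) {
    dmap <- setNames(days$days, days$year)
  } else {
    dmap <- NULL
  }
  g <- growth_by_year$mean_growth[match(july_fish$year,
                                        growth_by_year$year)]
  miss <- is.na(g)
  if (any(miss)) {
    warning("no July growth summary for year(s): ",
            paste(unique(july_fish$year[miss]), collapse = ", "),
            "; fish dropped")
    july_fish <- july_fish[!miss, , drop = FALSE]
    g <- g[!miss]
  }
  d <- if (is.null(dmap)) rep(days, nrow(july_fish))
  else unname(dmap[as.character(july_fish$year)])
  if (any(is.na(d) | d <= 0)) stop("missing or non-positive day count")
  july_fish$predicted_aug_mm <- switch(
    mode,
    multiplicative = july_fish$sl_mm * (1 + g)^d,
    additive = july_fish$sl_mm + d * g * mean(july_fish$sl_mm))
  july_fish
}

#' Compare predicted and observed August sizes
#'
#' Per year: percent gap `100 * (observed mean - predicted mean) /
#' predicted mean`; then mean and SE of the per-year gaps within each
#' class (the per-year-then-average order that produces "mean +/- SE"
#' summaries). 95% CIs on each year's means are normal-theory.
#'
#' @param predicted data.frame with `year`, `class`,
#'   `predicted_aug_mm`.
#' @param observed data.frame of August fish with `year`, `class`,
#'   `sl_mm`.
#' @return list: `by_year`, `by_class`, `pooled` (pooled-mean gap per
#'   class, for contrast with the per-year average).
#' @export
compare_predicted_observed <- function(predicted, observed) {
  predicted <- as.data.frame(predicted)
  observed <- as.data.frame(observed)
  years <- intersect(unique(predicted$year), unique(observed$year))
  rows <- lapply(years, function(y) {
    p <- predicted$predicted_aug_mm[predicted$year == y]
    o <- observed$sl_mm[observed$year == y]
    data.frame(year = y,
               class = predicted$class[predicted$year == y][1],
               pred_mean = mean(p), pred_lo = ci95(p)[1],
               pred_hi = ci95(p)[2],
               obs_mean = mean(o), obs_lo = ci95(o)[1],
               obs_hi = ci95(o)[2],
               pct_gap = 100 * (mean(o) - mean(p)) / mean(p))
  })
  by_year <- do.call(rbind, rows)
  by_class <- do.call(rbind, lapply(split(by_year, by_year$class),
                                    function(d) data.frame(
                                      class = d$class[1],
                                      mean_gap_pct = mean(d$pct_gap),
                                      se_gap_pct = std_error(d$pct_gap),
                                      n_years = nrow(d))))
  pooled <- do.call(rbind, lapply(split(by_year, by_year$class),
                                  function(d) {
    cls <- d$class[1]
    p <- predicted$predicted_aug_mm[predicted$class == cls &
                                      predicted$year %in% years]
    o <- observed$sl_mm[observed$class == cls & observed$year %in% years]
    data.frame(class = cls, pred_mean = mean(p), obs_mean = mean(o),
               pct_gap = 100 * (mean(o) - mean(p)) / mean(p))
  }))
  rownames(by_class) <- rownames(pooled) <- NULL
  list(by_year = by_year, by_class = by_class, pooled = pooled)
}

ci95 <- function(x) {
  se <- std_error(x)
  if (is.na(se)) return(c(NA_real_, NA_real_))
  mean(x) + c(-1, 1) * stats::qnorm(0.975) * se
}

#' Mean of the top-q fraction of an empirical distribution
#'
#' Tail expectation of the empirical distribution: observations sorted
#' decreasing each carry mass 1/n, with the boundary observation taken
#' fractionally, so `top_quantile_mean(x, k/n)` is the plain mean of
#' the k largest values and the function is monotone non-increasing in
#' q.
#'
#' @param x numeric values.
#' @param q fraction in (0, 1].
#' @return mean of the top-q mass of `x`.
#' @export
top_quantile_mean <- function(x, q) {
  stopifnot(q > 0, q <= 1)
  s <- sort(x, decreasing = TRUE)
  n <- length(s)
  w <- pmin(pmax(q * n - (seq_len(n) - 1), 0), 1)
  sum(s * w) / sum(w)
}

#' Survival quantile reconciling predicted and observed sizes
#'
#' Finds the largest fraction q such that the mean of the top-q
#' predicted August sizes is at least the observed August mean: the
#' "only the largest q survived" quantile. The search covers the
#' empirical grid `1/n, 2/n, ..., 1` plus the landmark quantiles, with
#' ties broken toward larger q (conservative survival). Also reports
#' the full q -> top-q-mean curve and, when an observed 95% CI is
#' supplied, whether it covers the top-q mean.
#'
#' @param predicted_sizes predicted August sizes, mm.
#' @param observed_mean observed August mean size, mm.
#' @param observed_ci optional length-2 observed 95% CI.
#' @param landmarks extra quantiles always included in the grid.
#' @return list: `q_star` (NA when the observed mean exceeds the
#'   maximum predicted size), `curve` (data.frame `q`, `top_mean`,
#'   `within_ci`), `observed_mean`.
#' @export
survival_quantile_search <- function(predicted_sizes, observed_mean,
                                     observed_ci = NULL,
                                     landmarks = c(0.15, 0.25)) {
  x <- predicted_sizes[is.finite(predicted_sizes)]
  if (length(x) < 2) stop("degenerate predicted sizes")
  n <- length(x)
  # grid means at k/n come from one cumulative sum; landmarks exactly
  s <- sort(x, decreasing = TRUE)
  grid_tm <- cumsum(s) / seq_len(n)
  extra <- setdiff(landmarks, seq_len(n) / n)
  qs <- c(seq_len(n) / n, extra)
  tm <- c(grid_tm, vapply(extra, function(q) top_quantile_mean(x, q),
                          numeric(1)))
  ord <- order(qs)
  qs <- qs[ord]; tm <- tm[ord]
  stopifnot(all(diff(tm) <= 1e-9))  # monotone non-increasing, checked
  within <- if (!is.null(observed_ci))
    tm >= observed_ci[1] & tm <= observed_ci[2] else NA
  curve <- data.frame(q = qs, top_mean = tm, within_ci = within)
  ok <- which(tm >= observed_mean)
  q_star <- if (length(ok)) max(qs[ok]) else NA_real_
  list(q_star = q_star, curve = curve, observed_mean = observed_mean)
}

#' Simulated-population survival-quantile analysis
#'
#' Builds truncated-normal populations of `n_pop` individuals for the
#' predicted and observed August size distributions, draws seeded
#' samples at the field sample sizes, and applies
#' [survival_quantile_search()] to the simulated predicted population
#' against the simulated observed sample mean.
#'
#' @param pred_mean,pred_sd predicted August size distribution, mm.
#' @param obs_mean,obs_sd observed August size distribution, mm.
#' @param n_pred,n_obs field sample sizes for the seeded draws.
#' @param n_pop population size (default 10000).
#' @param floor_mm lower truncation for lengths (default 20).
#' @param seed integer seed.
#' @return list: `q_star`, `curve`, `pred_population`, `obs_draw_mean`,
#'   `obs_draw_ci`, `pred_draw_mean`, `pred_draw_ci`.
#' @export
simulate_populations <- function(pred_mean, pred_sd, obs_mean, obs_sd,
                                 n_pred, n_obs, n_pop = 10000L,
                                 floor_mm = 20, seed = 1L) {
  if (pred_sd <= 0 || obs_sd <= 0) stop("population sd must be positive")
  if (n_pop < max(n_pred, n_obs)) stop("population smaller than sample")
  withr_seed(derive_seed(seed, "projection"), {
    rtnorm <- function(n, m, s) {
      x <- stats::rnorm(n, m, s)
      while (any(bad <- x < floor_mm))
        x[bad] <- stats::rnorm(sum(bad), m, s)
      x
    }
    pred_pop <- rtnorm(n_pop, pred_mean, pred_sd)
    obs_pop <- rtnorm(n_pop, obs_mean, obs_sd)
    pred_draw <- sample(pred_pop, n_pred)
    obs_draw <- sample(obs_pop, n_obs)
    sq <- survival_quantile_search(pred_pop, mean(obs_draw),
                                   observed_ci = ci95(obs_draw))
    list(q_star = sq$q_star, curve = sq$curve,
         pred_population = pred_pop,
         obs_draw_mean = mean(obs_draw), obs_draw_ci = ci95(obs_draw),
         pred_draw_mean = mean(pred_draw),
         pred_draw_ci = ci95(pred_draw))
  })
}
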