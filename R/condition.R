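#' Catch per unit effort by stratum
#'
#' Mean and standard error of per-haul counts within each stratum
#' (default year x month). Strata with a single haul report `se = NA`.
#'
#' @param hauls data.frame with `n_cod` counts and stratum columns.
#' @param by character vector of stratum column names.
#' @return data.frame with stratum columns, `n_hauls`, `cpue`, `se`.
#' @export
cpue <- function(hauls, by = c("year", "month")) {
  hauls <- as.data.frame(hauls)
  stopifnot("n_cod" %in% names(hauls), all(by %in% names(hauls)))
  if (any(hauls$n_cod < 0)) stop("negative haul count")
  key <- interaction(hauls[by], drop = TRUE)
  parts <- lapply(split(hauls, key), function(d) {
    cbind(d[1, by, drop = FALSE],
          data.frame(n_hauls = nrow(d), cpue = mean(d$n_cod),
                     se = std_error(d$n_cod)))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Hepatosomatic index
#'
#' HSI = 100 x liver wet weight / whole-body wet weight, a
#' lipid-storage condition proxy (percent).
#'
#' @param liver_g liver wet weight, g.
#' @param body_g whole-body wet weight, g.
#' @return HSI percent, vectorised.
#' @export
hsi <- function(liver_g, body_g) {
  if (any(body_g <= 0)) stop("body weight must be positive")
  if (any(liver_g < 0)) stop("negative liver weight")
  if (any(liver_g >= body_g)) stop("liver weight >= body weight")
  100 * liver_g / body_g
}

#' Pooled log-linear length-weight condition model
#'
#' OLS of ln(mass, g) on ln(standard length, mm) pooled across all
#' fish; residuals are the length-weight condition index. Returns the
#' coefficients with SEs and the adjusted R-squared.
#'
#' @param fish data.frame with `sl_mm` and `mass_g`.
#' @return list: `intercept`, `slope`, `intercept_se`, `slope_se`,
#'   `adj_r_squared`, `residuals`, and the underlying `fit`.
#' @export
lw_condition <- function(fish) {
  fish <- as.data.frame(fish)
  stopifnot(all(c("sl_mm", "mass_g") %in% names(fish)))
  if (nrow(fish) < 3) stop("need at least 3 fish for the length-weight fit")
  if (any(fish$sl_mm <= 0) || any(fish$mass_g <= 0))
    stop("lengths and masses must be positive")
  fit <- stats::lm(log(mass_g) ~ log(sl_mm), data = fish)
  s <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       intercept_se = s$coefficients[1, 2],
       slope_se = s$coefficients[2, 2],
       adj_r_squared = s$adj.r.squared,
       residuals = unname(stats::residuals(fit)),
       fit = fit)
}

#' Yearly minimum length and its relation to heatwave class
#'
#' Computes yearly minimum standard length per month and, per month,
#' fits the linear model `min_sl ~ class`. With one year per class the
#' model is saturated and flagged rather than tested.
#'
#' @param fish data.frame with `year`, `month`, `class`, `sl_mm`.
#' @param months months to analyse (default 7 and 8).
#' @return list per month: `minima` (year, class, min_sl), `class_means`,
#'   `fit` (lm or NULL), `saturated` flag, `p_value` (overall F, NA when
#'   saturated).
#' @export
min_length_by_year <- function(fish, months = c(7L, 8L)) {
  fish <- as.data.frame(fish)
  stopifnot(all(c("year", "month", "class", "sl_mm") %in% names(fish)))
  out <- list()
  for (m in months) {
    d <- fish[fish$month == m, ]
    if (nrow(d) == 0) next
    minima <- stats::aggregate(sl_mm ~ year + class, data = d, FUN = min)
    names(minima)[3] <- "min_sl"
    class_means <- stats::aggregate(min_sl ~ class, data = minima,
                                    FUN = mean)
    n_per_class <- table(minima$class)
    saturated <- all(n_per_class <= 1) ||
      nrow(minima) <= length(unique(minima$class))
    fit <- NULL; p <- NA_real_
    if (!saturated) {
      fit <- stats::lm(min_sl ~ class, data = minima)
      s <- summary(fit)
      if (!is.null(s$fstatistic))
        p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                       lower.tail = FALSE)
    }
    out[[as.character(m)]] <- list(minima = minima,
                                   class_means = class_means,
                                   fit = fit, saturated = saturated,
                                   p_value = unname(p))
  }
  out
}

#' July-to-August percent change, per year then by class
#'
#' Per year: 100 x (August mean - July mean) / July mean of `metric`;
#' then mean and SE of the per-year changes within each heatwave class.
#' Averaging per-year first is what produces "mean +/- SE" summaries
#' across years; years missing either month are excluded.
#'
#' @param fish data.frame with `year`, `month`, `class` and the metric
#'   column.
#' @param metric name of the metric column (default `"sl_mm"`).
#' @return list: `by_year` (year, class, jul_mean, aug_mean,
#'   pct_change), `by_class` (class, mean_pct, se_pct, n_years),
#'   `excluded_years`.
#' @export
percent_change_july_august <- function(fish, metric = "sl_mm") {
  fish <- as.data.frame(fish)
  stopifnot(all(c("year", "month", "class", metric) %in% names(fish)))
  years <- sort(unique(fish$year))
  rows <- list(); excluded <- integer()
  for (y in years) {
    jul <- fish[fish$year == y & fish$month == 7L, metric]
    aug <- fish[fish$year == y & fish$month == 8L, metric]
    if (length(jul) == 0 || length(aug) == 0) {
      excluded <- c(excluded, y)
      next
    }
    cls <- fish$class[fish$year == y][1]
    rows[[as.character(y)]] <- data.frame(
      year = y, class = cls, jul_mean = mean(jul), aug_mean = mean(aug),
      pct_change = 100 * (mean(aug) - mean(jul)) / mean(jul))
  }
  by_year <- do.call(rbind, rows)
  by_class <- NULL
  if (!is.null(by_year)) {
    parts <- lapply(split(by_year, by_year$class), function(d)
      data.frame(class = d$class[1], mean_pct = mean(d$pct_change),
                 se_pct = std_error(d$pct_change), n_years = nrow(d)))
    by_class <- do.call(rbind, parts)
    rownames(by_class) <- NULL
  }
  list(by_year = by_year, by_class = by_class, excluded_years = excluded)
}
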