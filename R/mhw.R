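#' Build a day-of-year climatology with a 90th-percentile threshold
#'
#' For each civil day of year (month-day, 365 slots), pools all baseline
#' temperatures falling within `window_half_width` days of that slot
#' (circular across the year boundary), takes the mean and the
#' `percentile`-th percentile, and smooths both with a circular moving
#' average of width `smooth_width`. Feb 29 is assigned the mean of the
#' Feb 28 and Mar 1 values. Percentiles use linear interpolation between
#' order statistics ([stats::quantile()] type 7) so the rule is pinned.
#'
#' @param series data.frame `date`, `temp_c`; strictly increasing dates,
#'   gaps allowed (missing days are simply absent from pools).
#' @param baseline integer vector of length 2, first and last baseline
#'   year (inclusive).
#' @param window_half_width half-width of the day-of-year pooling window
#'   (days, default 5 for an 11-day window).
#' @param smooth_width moving-average width in days (default 31).
#' @param percentile threshold percentile (default 90).
#' @return object of class `mhw_climatology`: data.frame `doy` (1-366),
#'   `clim_mean`, `threshold` plus the baseline attribute.
#' @export
build_climatology <- function(series, baseline,
                              window_half_width = 5L,
                              smooth_width = 31L,
                              percentile = 90) {
  series <- validate_temperature_series(series)
  stopifnot(length(baseline) == 2, baseline[1] <= baseline[2])
  yrs <- as.integer(format(series$date, "%Y"))
  base <- series[yrs >= baseline[1] & yrs <= baseline[2] &
                   !is.na(series$temp_c), ]
  if (nrow(base) == 0) stop("baseline period not covered by series")
  n_years <- length(unique(as.integer(format(base$date, "%Y"))))
  if (n_years < 10)
    warning("climatology baseline has fewer than 10 years (", n_years, ")")

  # civil day slots 1..365: Feb 29 observations are pooled with Feb 28
  slot <- civil_doy(base$date)
  pools_mean <- numeric(365)
  pools_q <- numeric(365)
  half <- window_half_width
  for (d in 1:365) {
    win <- ((d - half - 1):(d + half - 1)) %% 365 + 1
    vals <- base$temp_c[slot %in% win]
    if (length(vals) == 0) stop("empty climatology window at day ", d)
    pools_mean[d] <- mean(vals)
    pools_q[d] <- stats::quantile(vals, percentile / 100, names = FALSE,
                                  type = 7)
  }
  clim_mean <- circular_moving_average(pools_mean, smooth_width)
  thresh <- circular_moving_average(pools_q, smooth_width)

  # expand to 366-slot table; Feb 29 (doy 60 in leap layout) interpolated
  out <- data.frame(doy = 1:366,
                    clim_mean = c(clim_mean[1:59],
                                  mean(clim_mean[c(59, 60)]),
                                  clim_mean[60:365]),
                    threshold = c(thresh[1:59],
                                  mean(thresh[c(59, 60)]),
                                  thresh[60:365]))
  structure(out, class = c("mhw_climatology", "data.frame"),
            baseline = as.integer(baseline), percentile = percentile)
}

# day-of-year on a fixed 365-day civil calendar (Feb 29 -> slot of Feb 28)
civil_doy <- function(dates) {
  md <- format(dates, "%m-%d")
  ref <- format(seq(as.Date("2001-01-01"), as.Date("2001-12-31"), "day"),
                "%m-%d")
  out <- match(md, ref)
  out[md == "02-29"] <- match("02-28", ref)
  out
}

# leap-aware 366-slot index into the climatology table
clim_doy <- function(dates) {
  md <- format(dates, "%m-%d")
  ref <- format(seq(as.Date("2000-01-01"), as.Date("2000-12-31"), "day"),
                "%m-%d")
  match(md, ref)
}

#' Detect marine heatwave events
#'
#' An event is a maximal run of at least `min_duration` consecutive days
#' with temperature strictly above the day-of-year threshold; qualifying
#' events separated by at most `max_gap` below-threshold days are merged.
#' Gap days count toward duration; cumulative intensity sums daily
#' anomalies (temp minus climatological mean) only over above-threshold
#' days, so it stays non-negative. Each event is categorised by the
#' largest integer multiple of the local (threshold - mean) gap its peak
#' anomaly reaches: 1 Moderate, 2 Strong, 3 Severe, >= 4 Extreme.
#'
#' @param series data.frame `date`, `temp_c`.
#' @param clim an `mhw_climatology`.
#' @param min_duration minimum event length in days (default 5).
#' @param max_gap maximum below-threshold gap joined (default 2).
#' @return data.frame, one row per event: `start`, `end`,
#'   `duration_days`, `max_intensity_c`, `cum_intensity_c_days`,
#'   `category`. Zero rows when nothing qualifies.
#' @export
detect_events <- function(series, clim, min_duration = 5L, max_gap = 2L) {
  series <- validate_temperature_series(series)
  stopifnot(inherits(clim, "mhw_climatology"))
  idx <- clim_doy(series$date)
  thr <- clim$threshold[idx]
  mu <- clim$clim_mean[idx]
  anom <- series$temp_c - mu
  above <- !is.na(series$temp_c) & series$temp_c > thr
  # contiguity: break runs across date gaps
  day_gap <- c(1, as.integer(diff(series$date)))
  run_id <- cumsum(!above | day_gap != 1)
  runs <- NULL
  if (any(above)) {
    spans <- tapply(seq_along(above)[above], run_id[above], range)
    runs <- do.call(rbind, lapply(spans, function(r)
      data.frame(s = r[1], e = r[2])))
    runs <- runs[runs$e - runs$s + 1 >= min_duration, , drop = FALSE]
  }
  if (is.null(runs) || nrow(runs) == 0)
    return(empty_events())
  runs <- runs[order(runs$s), , drop = FALSE]
  # merge qualifying runs separated by <= max_gap days (same date spacing)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap_days <- as.integer(series$date[runs$s[i]] -
                               series$date[merged$e[nrow(merged)]]) - 1L
      if (gap_days <= max_gap && gap_days >= 0) {
        merged$e[nrow(merged)] <- runs$e[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  ev <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$s[i]; e <- merged$e[i]
    span <- s:e
    hot <- span[above[span]]
    peak_i <- hot[which.max(anom[hot])]
    cat <- tryCatch(categorize(max(anom[hot]),
                               thr[peak_i] - mu[peak_i]),
                    error = function(e) {
                      warning("event at ", format(series$date[s]),
                              ": ", conditionMessage(e))
                      NA_character_
                    })
    data.frame(start = series$date[s], end = series$date[e],
               duration_days = as.integer(series$date[e] - series$date[s]) + 1L,
               max_intensity_c = max(anom[hot]),
               cum_intensity_c_days = sum(anom[hot]),
               category = cat)
  })
  do.call(rbind, ev)
}

empty_events <- function() {
  data.frame(start = as.Date(character()), end = as.Date(character()),
             duration_days = integer(), max_intensity_c = numeric(),
             cum_intensity_c_days = numeric(), category = character())
}

#' Categorise a heatwave peak anomaly
#'
#' Category is the largest integer multiple of the local
#' threshold-minus-climatology gap reached by the peak anomaly:
#' 1 Moderate, 2 Strong, 3 Severe, >= 4 Extreme.
#'
#' @param peak_anomaly_c peak temperature anomaly above the
#'   climatological mean, deg C.
#' @param gap_c threshold minus climatological mean at the peak day,
#'   deg C; must be positive.
#' @return category string.
#' @export
categorize <- function(peak_anomaly_c, gap_c) {
  if (gap_c <= 0)
    stop("degenerate climatology: threshold equals mean at the peak day")
  k <- floor(peak_anomaly_c / gap_c)
  if (k >= 4) "Extreme" else
    c("Moderate", "Moderate", "Strong", "Severe")[min(k, 3) + 1]
}

#' Count heatwave days and classify years
#'
#' Counts, per calendar year, the number of days falling inside detected
#' MHW events, then bins years into the three study classes: a year with
#' at least `day_threshold` event days is `Heatwave`; a non-heatwave
#' year occurring after the first heatwave year is `Between`; all
#' earlier years are `Before`.
#'
#' @param events event table from [detect_events()].
#' @param years integer vector of analysis years (must all be covered).
#' @param day_threshold minimum event days for a Heatwave year
#'   (default 90).
#' @return data.frame `year`, `heatwave_days`, `class`.
#' @export
classify_years <- function(events, years, day_threshold = 90L) {
  years <- sort(as.integer(years))
  counts <- setNames(integer(length(years)), years)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      days <- seq(events$start[i], events$end[i], by = "day")
      tab <- table(format(days, "%Y"))
      for (y in names(tab)) {
        if (y %in% names(counts)) counts[y] <- counts[y] + tab[[y]]
      }
    }
  }
  cls <- rep("Before", length(years))
  hw <- counts >= day_threshold
  cls[hw] <- "Heatwave"
  if (any(hw)) {
    first_hw <- min(which(hw))
    cls[!hw & seq_along(years) > first_hw] <- "Between"
  }
  data.frame(year = years, heatwave_days = as.integer(counts), class = cls)
}

#' Reference year-class mapping used for validation
#'
#' Loads the study's published year binning (2006-2013 Before;
#' 2014-2016 and 2019 Heatwave; 2017-2018 Between), shipped as a text
#' fixture for validating classification output format and joins.
#'
#' @return data.frame `year`, `class`.
#' @export
reference_year_classes <- function() {
  path <- system.file("extdata", "heatwave_year_classes.csv",
                      package = "codnursery")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

validate_temperature_series <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("date", "temp_c") %in% names(series)))
    stop("temperature series needs columns date, temp_c")
  series$date <- as.Date(series$date)
  if (is.unsorted(series$date, strictly = TRUE))
    stop("temperature series dates must be strictly increasing")
  series
}
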