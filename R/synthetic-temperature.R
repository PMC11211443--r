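#' Describe a synthetic daily temperature regime
#'
#' A temperature scenario is a seasonal sinusoid plus stationary AR(1)
#' noise, with optional additive anomaly blocks that emulate heatwave
#' forcing. It is the substrate for the climatology / event-detection
#' stage, standing in for a multi-decade nearshore logger series.
#'
#' @param start_date,end_date `Date` (or coercible) bounds, inclusive.
#' @param mean_annual long-term mean temperature, deg C.
#' @param seasonal_amplitude half-range of the seasonal cycle, deg C.
#' @param phase_day day-of-year at which the seasonal maximum occurs.
#' @param ar1_phi lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param noise_sd marginal SD of the AR(1) noise, deg C.
#' @param anomalies data.frame with columns `start_date`, `duration_days`,
#'   `intensity_c` (deg C added on those days); overlapping blocks add.
#' @param seed integer seed for the noise stream.
#' @return an object of class `temperature_scenario`.
#' @export
temperature_scenario <- function(start_date, end_date,
                                 mean_annual = 8,
                                 seasonal_amplitude = 4,
                                 phase_day = 227,
                                 ar1_phi = 0.8,
                                 noise_sd = 0.6,
                                 anomalies = NULL,
                                 seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end_date before start_date")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(anomalies)) {
    anomalies <- as.data.frame(anomalies)
    stopifnot(all(c("start_date", "duration_days", "intensity_c") %in%
                    names(anomalies)))
    anomalies$start_date <- as.Date(anomalies$start_date)
    if (any(anomalies$intensity_c < 0)) stop("anomaly intensity must be >= 0")
    if (any(anomalies$duration_days < 1)) stop("anomaly duration must be >= 1")
  }
  structure(list(start_date = start_date, end_date = end_date,
                 mean_annual = mean_annual,
                 seasonal_amplitude = seasonal_amplitude,
                 phase_day = phase_day, ar1_phi = ar1_phi,
                 noise_sd = noise_sd, anomalies = anomalies,
                 seed = as.integer(seed)),
            class = "temperature_scenario")
}

#' Generate a daily temperature series
#'
#' Realises a [temperature_scenario()] as one record per calendar day:
#' seasonal sinusoid + stationary AR(1) noise + anomaly blocks added on
#' their dates. Identical scenario and seed give an identical series.
#'
#' @param scenario a `temperature_scenario`.
#' @return data.frame with columns `date` (Date) and `temp_c`.
#' @export
generate_temperature <- function(scenario) {
  stopifnot(inherits(scenario, "temperature_scenario"))
  dates <- seq(scenario$start_date, scenario$end_date, by = "day")
  n <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  seasonal <- scenario$mean_annual + scenario$seasonal_amplitude *
    cos(2 * pi * (doy - scenario$phase_day) / 365.25)
  noise <- withr_seed(scenario$seed, ar1_noise(n, scenario$ar1_phi,
                                               scenario$noise_sd))
  temp <- seasonal + noise
  if (!is.null(scenario$anomalies)) {
    for (i in seq_len(nrow(scenario$anomalies))) {
      a <- scenario$anomalies[i, ]
      days <- seq(a$start_date, by = "day", length.out = a$duration_days)
      temp[dates %in% days] <- temp[dates %in% days] + a$intensity_c
    }
  }
  data.frame(date = dates, temp_c = temp)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
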