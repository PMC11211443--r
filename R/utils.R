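#' @keywords internal
"_PACKAGE"

# Per-stage seed derivation: all randomness flows from one root seed via
# named substreams, so toggling stages leaves the others reproducible.
.stage_offsets <- c(
  temperature = 101L, cohort = 202L, survival = 303L, diet = 404L,
  community = 505L, models = 606L, projection = 707L, pipeline = 808L
)

derive_seed <- function(root_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  # keep within 32-bit signed range
  as.integer((as.numeric(root_seed) * 1009 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circular moving average
#'
#' Moving average of a vector treated as circular (wrap-around at both
#' ends), used to smooth day-of-year climatologies across the year
#' boundary.
#'
#' @param x numeric vector.
#' @param width odd window width (number of elements averaged).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
circular_moving_average <- function(x, width) {
  stopifnot(width >= 1, width %% 2 == 1)
  n <- length(x)
  if (width == 1 || n == 1) return(x)
  half <- (width - 1) / 2
  idx <- outer(seq_len(n), -half:half, function(i, k) ((i + k - 1) %% n) + 1)
  rowMeans(matrix(x[idx], nrow = n))
}

# Stationary AR(1) noise: first draw from the marginal distribution so
# short windows carry no burn-in artifact.
ar1_noise <- function(n, phi, sd) {
  stopifnot(phi >= 0, phi < 1, sd >= 0, n >= 1)
  if (sd == 0) return(rep(0, n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov_sd <- sd * sqrt(1 - phi^2)
    for (t in 2:n) e[t] <- phi * e[t - 1] + stats::rnorm(1, 0, innov_sd)
  }
  e
}

# standard error of a mean; NA for n < 2 (matches "single haul -> SE missing")
std_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
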