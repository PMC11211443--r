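#' Biological Intercept back-calculation parameters
#'
#' Defaults are the published biological intercept for Pacific cod:
#' length 3.9 mm at otolith radius 8.3 um.
#'
#' @param L0 length at the biological intercept, mm.
#' @param O0 otolith radius at the biological intercept, um.
#' @return list with class `backcalc_params`.
#' @export
backcalc_params <- function(L0 = 3.9, O0 = 8.3) {
  if (L0 <= 0 || O0 <= 0) stop("L0 and O0 must be positive")
  structure(list(L0 = L0, O0 = O0), class = "backcalc_params")
}

#' Back-calculate daily standard length from otolith radii
#'
#' Biological Intercept model: length at age a is
#' `L_a = L_c + (O_a - O_c) * (L_c - L0) / (O_c - O0)`,
#' a line through (O0, L0) and the capture point (O_c, L_c). Radii in
#' um, lengths in mm; no implicit unit conversion anywhere.
#'
#' @param radii_um increasing vector of cumulative otolith radii, um.
#' @param capture_radius_um otolith radius at capture, um (must be >= all
#'   `radii_um` and > `O0`).
#' @param capture_length_mm standard length at capture, mm (> `L0`).
#' @param params a [backcalc_params()].
#' @param fish_id optional id used in error messages.
#' @return numeric vector of back-calculated lengths, mm.
#' @export
back_calculate_lengths <- function(radii_um, capture_radius_um,
                                   capture_length_mm,
                                   params = backcalc_params(),
                                   fish_id = NULL) {
  stopifnot(inherits(params, "backcalc_params"))
  id <- if (is.null(fish_id)) "" else paste0(" (fish ", fish_id, ")")
  if (capture_radius_um <= params$O0)
    stop("capture radius <= O0: degenerate denominator", id)
  if (capture_length_mm <= params$L0)
    stop("capture length <= L0", id)
  if (any(diff(radii_um) <= 0))
    stop("otolith radii must be strictly increasing", id)
  if (any(radii_um > capture_radius_um + 1e-9))
    stop("increment radius exceeds capture radius", id)
  capture_length_mm + (radii_um - capture_radius_um) *
    (capture_length_mm - params$L0) / (capture_radius_um - params$O0)
}

#' Daily relative growth over the pre-capture window
#'
#' Backward-difference proportional growth `g_t = (L_t - L_{t-1}) /
#' L_{t-1}` (mm/mm/day) over the final `window` days before capture.
#' Increments are numbered 1..window with `window` the day before
#' capture, so increment 11 is the midpoint of the default 21-day
#' window. Tracks shorter than the window are retained and flagged
#' rather than dropped.
#'
#' @param lengths_mm daily back-calculated lengths, oldest first; the
#'   last element is the length at capture.
#' @param window analysis window in days (default 21).
#' @return data.frame `increment_index`, `length_mm`, `rel_growth`, with
#'   attribute `truncated` (TRUE when fewer than `window` increments
#'   were available).
#' @export
relative_growth <- function(lengths_mm, window = 21L) {
  n <- length(lengths_mm)
  if (n < 2) stop("need at least two daily lengths")
  g <- diff(lengths_mm) / lengths_mm[-n]
  k <- length(g)
  truncated <- k < window
  if (truncated)
    warning("only ", k, " increments available for a ", window,
            "-day window; track truncated")
  use <- max(1L, k - window + 1L):k
  out <- data.frame(increment_index = window - rev(seq_along(use)) + 1L,
                    length_mm = lengths_mm[use + 1L],
                    rel_growth = g[use])
  attr(out, "truncated") <- truncated
  out
}

#' Replicate-read quality control for otolith counts
#'
#' Flags fish whose independent increment counts differ by more than 10%
#' (relative range, (max - min)/mean). No fish are discarded; single
#' reads are flagged unverifiable.
#'
#' @param reads data.frame `fish_id`, `count` with one row per read.
#' @param tolerance relative-range flag threshold (default 0.10).
#' @return data.frame `fish_id`, `n_reads`, `discrepancy`, `flagged`,
#'   `unverifiable`.
#' @export
qc_replicate_reads <- function(reads, tolerance = 0.10) {
  stopifnot(all(c("fish_id", "count") %in% names(reads)))
  by_fish <- split(reads$count, reads$fish_id)
  out <- lapply(names(by_fish), function(id) {
    x <- by_fish[[id]]
    if (length(x) < 2) {
      data.frame(fish_id = id, n_reads = length(x), discrepancy = NA_real_,
                 flagged = FALSE, unverifiable = TRUE)
    } else {
      d <- (max(x) - min(x)) / mean(x)
      data.frame(fish_id = id, n_reads = length(x), discrepancy = d,
                 flagged = d > tolerance, unverifiable = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Back-calculate growth tracks for a whole otolith table
#'
#' Applies [back_calculate_lengths()] and [relative_growth()] per fish
#' over the standard otolith table (long format, increment 0 = window
#' start).
#'
#' @param otoliths data.frame `fish_id`, `increment_index`, `radius_um`,
#'   `radius_at_capture_um`.
#' @param fish data.frame with `fish_id` and `sl_mm` (capture length).
#' @param params a [backcalc_params()].
#' @param window analysis window, days.
#' @return data.frame `fish_id`, `increment_index`, `length_mm`,
#'   `rel_growth`.
#' @export
growth_tracks <- function(otoliths, fish, params = backcalc_params(),
                          window = 21L) {
  stopifnot(all(c("fish_id", "increment_index", "radius_um",
                  "radius_at_capture_um") %in% names(otoliths)),
            all(c("fish_id", "sl_mm") %in% names(fish)))
  out <- lapply(split(otoliths, otoliths$fish_id), function(tr) {
    tr <- tr[order(tr$increment_index), ]
    id <- tr$fish_id[1]
    lc <- fish$sl_mm[match(id, fish$fish_id)]
    if (is.na(lc)) stop("fish ", id, " missing from fish table")
    L <- back_calculate_lengths(tr$radius_um, tr$radius_at_capture_um[1],
                                lc, params, fish_id = id)
    g <- relative_growth(L, window = window)
    cbind(fish_id = id, g, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
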