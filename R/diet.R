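#' Stomach fullness index
#'
#' Fullness = content weight / (total fish weight - content weight),
#' both in grams. A square-root transform is available for modelling
#' (zero-inflated fullness values); data are stored untransformed.
#'
#' @param content_g stomach content weight, g.
#' @param fish_total_g whole fish weight including contents, g.
#' @param sqrt_transform if TRUE return `sqrt(fullness)`.
#' @return fullness (proportion), vectorised.
#' @export
stomach_fullness <- function(content_g, fish_total_g,
                             sqrt_transform = FALSE) {
  if (any(content_g < 0)) stop("negative content weight")
  if (any(fish_total_g <= content_g))
    stop("stomach content weight >= total fish weight")
  f <- content_g / (fish_total_g - content_g)
  if (sqrt_transform) sqrt(f) else f
}

#' Prey-Specific Index of Relative Importance (PSIRI)
#'
#' For each prey taxon i over the analyzed (non-empty, biotic) stomachs:
#' \itemize{
#'   \item \%FO_i: percent of stomachs containing i;
#'   \item \%PN_i: percent-by-number of i averaged over only the
#'     stomachs containing i (prey-specific percent number);
#'   \item \%PW_i: the same by weight;
#'   \item \%PSIRI_i = \%FO_i x (\%PN_i + \%PW_i) / 200.
#' }
#' The /200 (rather than /2) keeps all four quantities on the 0-100
#' scale while preserving the defining identity that PSIRI sums to 100
#' over taxa. Empty stomachs and abiotic items must be removed before
#' calling (see `drop_abiotic`/filtering in [psiri_matrix()]).
#'
#' @param stomachs data.frame with columns `fish_id`, `prey_taxon`,
#'   `count`, `weight_mg`; one row per prey taxon per stomach. Fish with
#'   no rows are not represented (an empty stomach contributes nothing).
#' @return data.frame `prey_taxon`, `fo_pct`, `pn_pct`, `pw_pct`,
#'   `psiri_pct`, sorted by decreasing PSIRI.
#' @export
psiri <- function(stomachs) {
  stomachs <- as.data.frame(stomachs)
  need <- c("fish_id", "prey_taxon", "count", "weight_mg")
  stopifnot(all(need %in% names(stomachs)))
  stomachs <- stomachs[stomachs$count > 0 | stomachs$weight_mg > 0, ]
  if (nrow(stomachs) == 0) stop("all stomachs empty: PSIRI undefined")
  mat <- psiri_stomach_shares(stomachs)
  n <- nrow(mat$num)
  fo <- 100 * colMeans(mat$num > 0 | mat$wt > 0)
  pn <- vapply(seq_len(ncol(mat$num)), function(j) {
    occ <- mat$num[, j] > 0 | mat$wt[, j] > 0
    mean(mat$num[occ, j])
  }, numeric(1))
  pw <- vapply(seq_len(ncol(mat$wt)), function(j) {
    occ <- mat$num[, j] > 0 | mat$wt[, j] > 0
    mean(mat$wt[occ, j])
  }, numeric(1))
  out <- data.frame(prey_taxon = colnames(mat$num), fo_pct = fo,
                    pn_pct = pn, pw_pct = pw,
                    psiri_pct = fo * (pn + pw) / 200)
  out <- out[order(-out$psiri_pct), ]
  rownames(out) <- NULL
  out
}

# per-stomach percent-by-number and percent-by-weight matrices
psiri_stomach_shares <- function(stomachs) {
  ids <- unique(stomachs$fish_id)
  taxa <- sort(unique(stomachs$prey_taxon))
  num <- wt <- matrix(0, length(ids), length(taxa),
                      dimnames = list(ids, taxa))
  cnt <- tapply(stomachs$count, list(stomachs$fish_id, stomachs$prey_taxon),
                sum)
  wgt <- tapply(stomachs$weight_mg,
                list(stomachs$fish_id, stomachs$prey_taxon), sum)
  cnt[is.na(cnt)] <- 0; wgt[is.na(wgt)] <- 0
  num[rownames(cnt), colnames(cnt)] <- cnt
  wt[rownames(wgt), colnames(wgt)] <- wgt
  num <- 100 * num / pmax(rowSums(num), .Machine$double.eps)
  wt <- 100 * wt / pmax(rowSums(wt), .Machine$double.eps)
  list(num = num, wt = wt)
}

#' Per-stomach PSIRI composition matrix
#'
#' Stomach-by-taxon matrix of per-stomach PSIRI percent, defined as the
#' mean of the stomach's percent-by-number and percent-by-weight for
#' each taxon; every row sums to 100. This is the community matrix used
#' by the Bray-Curtis / MRPP / indicator-species stage.
#'
#' @inheritParams psiri
#' @param grouping optional named character vector mapping taxon to
#'   group (e.g. the output of [apply_grouping_threshold()]); unmapped
#'   taxa keep their own name.
#' @return numeric matrix, rownames = fish ids, colnames = groups.
#' @export
psiri_matrix <- function(stomachs, grouping = NULL) {
  stomachs <- as.data.frame(stomachs)
  stomachs <- stomachs[stomachs$count > 0 | stomachs$weight_mg > 0, ]
  if (nrow(stomachs) == 0) stop("all stomachs empty")
  if (!is.null(grouping)) {
    mapped <- grouping[stomachs$prey_taxon]
    stomachs$prey_taxon <- ifelse(is.na(mapped), stomachs$prey_taxon, mapped)
  }
  mat <- psiri_stomach_shares(stomachs)
  (mat$num + mat$wt) / 2
}

#' Merge minor taxa into an "Other" group by PSIRI threshold
#'
#' Taxa whose PSIRI is at or below `threshold` percent are merged into a
#' single "Other" group. PSIRI is additive under pooling (per-stomach
#' shares add), so the merged table is recomputed from the stomach
#' records and the total stays at 100.
#'
#' @inheritParams psiri
#' @param threshold PSIRI percent below-or-at which a taxon is merged
#'   (default 3.5).
#' @param other_label label for the merged group.
#' @return list with `composition` (as [psiri()], on merged groups) and
#'   `grouping` (named character vector taxon -> group).
#' @export
apply_grouping_threshold <- function(stomachs, threshold = 3.5,
                                     other_label = "Other") {
  full <- psiri(stomachs)
  keep <- full$prey_taxon[full$psiri_pct > threshold]
  grouping <- setNames(ifelse(full$prey_taxon %in% keep,
                              full$prey_taxon, other_label),
                       full$prey_taxon)
  merged <- stomachs
  merged$prey_taxon <- grouping[merged$prey_taxon]
  list(composition = psiri(merged), grouping = grouping)
}

#' Empty-stomach summary
#'
#' Counts and percentages of empty stomachs, overall and stratified.
#'
#' @param fish_ids ids of all diet-analyzed fish.
#' @param empty logical vector parallel to `fish_ids`.
#' @param strata optional data.frame of stratifiers (e.g. month, class)
#'   parallel to `fish_ids`.
#' @return list with `overall` (n, n_empty, pct_empty) and optionally
#'   `by_stratum`.
#' @export
empty_stomach_summary <- function(fish_ids, empty, strata = NULL) {
  stopifnot(length(fish_ids) == length(empty))
  overall <- data.frame(n = length(empty), n_empty = sum(empty),
                        pct_empty = 100 * mean(empty))
  out <- list(overall = overall)
  if (!is.null(strata)) {
    strata <- as.data.frame(strata)
    agg <- stats::aggregate(empty, by = strata,
                            FUN = function(e)
                              c(n = length(e), n_empty = sum(e),
                                pct_empty = 100 * mean(e)))
    out$by_stratum <- do.call(data.frame, agg)
  }
  out
}
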