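#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` on non-negative rows;
#' a semi-metric in `[0, 1]`.
#'
#' @param mat samples x taxa numeric matrix, non-negative.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative entries")
  rs <- rowSums(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      denom <- rs[i] + rs[j]
      if (denom == 0)
        stop("two all-zero rows: Bray-Curtis undefined (rows ", i, ", ", j, ")")
      d[i, j] <- d[j, i] <- sum(abs(mat[i, ] - mat[j, ])) / denom
    }
  }
  d
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether within-group dissimilarities are smaller than expected
#' under random labelling. Observed delta is the group-size-weighted
#' (`n_g / sum(n_g)`) mean of within-group mean distances; the expected
#' delta is the mean of delta over label permutations; the
#' chance-corrected agreement is `A = 1 - observed / expected`; the
#' p-value is the add-one permutation tail `(1 + #{delta_perm <=
#' delta_obs}) / (n_perm + 1)`.
#'
#' @param d dissimilarity matrix (square symmetric) or `dist`.
#' @param labels group labels, length `nrow(d)`; each group needs >= 2
#'   members.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list: `A`, `observed_delta`, `expected_delta`, `p_value`,
#'   `n_perm`, `perm_deltas`.
#' @export
mrpp <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(nrow(d) == length(labels))
  sizes <- table(labels)
  if (length(sizes) < 2) stop("MRPP needs at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two members")
  delta <- function(lab) {
    w <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d[idx, idx]
      w <- w + length(idx) * mean(sub[lower.tri(sub)])
    }
    w / length(lab)
  }
  obs <- delta(labels)
  perm <- withr_seed(seed, vapply(seq_len(n_perm), function(i)
    delta(sample(labels)), numeric(1)))
  expected <- mean(perm)
  list(A = 1 - obs / expected, observed_delta = obs,
       expected_delta = expected,
       p_value = (1 + sum(perm <= obs)) / (n_perm + 1),
       n_perm = n_perm, perm_deltas = perm)
}

#' Indicator species analysis (IndVal)
#'
#' Dufrene-Legendre indicator values: for taxon i and group g,
#' `IndVal = 100 * specificity * fidelity` where specificity is the
#' group's mean abundance of i over the sum of all groups' mean
#' abundances, and fidelity is the fraction of the group's samples
#' containing i. Significance is a Monte Carlo test on each taxon's
#' maximum IndVal over groups (add-one rule).
#'
#' @param mat samples x taxa abundance matrix, non-negative.
#' @param labels group labels, length `nrow(mat)`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list: `indval` (taxa x groups matrix), `max_group`,
#'   `max_indval`, `p_value` (per taxon).
#' @export
indicator_species <- function(mat, labels, n_perm = 999L, seed = 1L) {
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  stopifnot(nrow(mat) == length(labels))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("ISA needs at least two groups")
  indval_mat <- function(lab) {
    mean_ab <- vapply(groups, function(g)
      colMeans(mat[lab == g, , drop = FALSE]), numeric(ncol(mat)))
    mean_ab <- matrix(mean_ab, ncol = length(groups),
                      dimnames = list(colnames(mat), groups))
    denom <- rowSums(mean_ab)
    spec <- mean_ab / ifelse(denom == 0, 1, denom)
    fid <- vapply(groups, function(g)
      colMeans(mat[lab == g, , drop = FALSE] > 0), numeric(ncol(mat)))
    fid <- matrix(fid, ncol = length(groups),
                  dimnames = list(colnames(mat), groups))
    100 * spec * fid
  }
  obs <- indval_mat(labels)
  obs_max <- apply(obs, 1, max)
  exceed <- withr_seed(seed, {
    cnt <- numeric(ncol(mat))
    for (b in seq_len(n_perm)) {
      pm <- apply(indval_mat(sample(labels)), 1, max)
      cnt <- cnt + (pm >= obs_max)
    }
    cnt
  })
  absent <- colSums(mat) == 0
  p <- (1 + exceed) / (n_perm + 1)
  p[absent] <- 1
  list(indval = obs,
       max_group = colnames(obs)[apply(obs, 1, which.max)],
       max_indval = obs_max, p_value = setNames(p, colnames(mat)))
}
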