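# Shared fixture builders; everything is generated in code at test time.

# flat temperature series at a constant value
flat_series <- function(value = 10, start = "2000-01-01",
                        end = "2012-12-31") {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  data.frame(date = dates, temp_c = rep(value, length(dates)))
}

# two-stomach toy: taxon A only in stomach 1, taxon B only in stomach 2
two_stomach_toy <- function() {
  data.frame(fish_id = c("s1", "s2"), prey_taxon = c("A", "B"),
             count = c(3L, 5L), weight_mg = c(2.0, 7.5))
}

# random stomach table with k taxa over n stomachs (all non-empty)
random_stomachs <- function(n = 12, k = 4, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    taxa <- sample(LETTERS[1:k], sample(1:k, 1))
    data.frame(fish_id = paste0("s", i), prey_taxon = taxa,
               count = sample(1:9, length(taxa), replace = TRUE),
               weight_mg = stats::runif(length(taxa), 0.1, 20))
  })
  do.call(rbind, rows)
}

# tiny two-group composition matrix with perfect separation
separated_matrix <- function() {
  m <- rbind(matrix(rep(c(80, 20, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(0, 20, 80), 3), 3, byrow = TRUE))
  colnames(m) <- c("A", "B", "C")
  rownames(m) <- paste0("s", 1:6)
  m
}

# exhaustive MRPP oracle: exact expected delta and p over all distinct
# label assignments (independent of the package implementation)
mrpp_exhaustive <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  sizes <- table(labels)
  delta <- function(lab) {
    w <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d[idx, idx]
      w <- w + length(idx) * mean(sub[lower.tri(sub)])
    }
    w / n
  }
  # enumerate all assignments of positions to the first group (2 groups)
  stopifnot(length(sizes) == 2)
  g1 <- names(sizes)[1]
  combos <- utils::combn(n, sizes[[1]])
  deltas <- apply(combos, 2, function(idx) {
    lab <- rep(names(sizes)[2], n); lab[idx] <- g1
    delta(lab)
  })
  obs <- delta(labels)
  list(observed = obs, expected = mean(deltas),
       A = 1 - obs / mean(deltas),
       p_exact = mean(deltas <= obs + 1e-12))
}

# closed-form mean of the top-q fraction of a normal distribution
normal_top_q_mean <- function(mu, sigma, q) {
  z <- stats::qnorm(1 - q)
  mu + sigma * stats::dnorm(z) / q
}
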