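#' Describe class- and month-specific diet mixtures
#'
#' One row per (class, month, prey taxon): the taxon's draw
#' probability, the mean item count per occurrence, and the per-item
#' weight distribution (lognormal, parametrized by mean and SD in mg so
#' weights are strictly positive and right-skewed like real prey
#' masses). `empty_probability` and `items_mean` are per (class,
#' month) and must be constant within a stratum.
#'
#' @param profile data.frame with columns `class`, `month`,
#'   `prey_taxon`, `prob`, `weight_mean_mg`, `weight_sd_mg`,
#'   `empty_probability`, `items_mean`.
#' @return object of class `diet_profile`.
#' @export
diet_profile <- function(profile) {
  profile <- as.data.frame(profile)
  need <- c("class", "month", "prey_taxon", "prob", "weight_mean_mg",
            "weight_sd_mg", "empty_probability", "items_mean")
  stopifnot(all(need %in% names(profile)))
  if (any(profile$empty_probability < 0 | profile$empty_probability > 1))
    stop("empty_probability must be in [0, 1]")
  key <- interaction(profile$class, profile$month, drop = TRUE)
  psum <- tapply(profile$prob, key, sum)
  if (any(abs(psum - 1) > 1e-8))
    stop("prey probabilities must sum to 1 within each (class, month)")
  structure(profile, class = c("diet_profile", "data.frame"))
}

#' Generate stomach contents for a fish table
#'
#' Per fish: empty with the stratum's stated probability, otherwise
#' `1 + Poisson(items_mean - 1)` prey items assigned to taxa by a
#' multinomial draw, each with a lognormal item weight. Stomach content
#' weight is the sum of item weights; `fish_total_g` is taken from the
#' fish table's `mass_g`.
#'
#' @param fish fish data.frame (`fish_id`, `class`, `month`, `mass_g`).
#' @param profile a [diet_profile()]; every (class, month) present in
#'   `fish` must be covered.
#' @param seed integer seed.
#' @return data.frame `fish_id`, `prey_taxon`, `count`, `weight_mg`,
#'   `stomach_total_g`, `fish_total_g`; empty stomachs appear as a
#'   single row with `prey_taxon = NA` and zero count/weight.
#' @export
generate_diets <- function(fish, profile, seed = 1L) {
  stopifnot(inherits(profile, "diet_profile"))
  fish <- as.data.frame(fish)
  strata <- unique(fish[c("class", "month")])
  pkey <- paste(profile$class, profile$month)
  missing <- setdiff(paste(strata$class, strata$month), pkey)
  if (length(missing))
    stop("diet profile missing for: ", paste(missing, collapse = "; "))
  withr_seed(derive_seed(seed, "diet"), {
    rows <- lapply(seq_len(nrow(fish)), function(i) {
      f <- fish[i, ]
      pr <- profile[pkey == paste(f$class, f$month), ]
      if (stats::runif(1) < pr$empty_probability[1]) {
        return(data.frame(fish_id = f$fish_id, prey_taxon = NA_character_,
                          count = 0L, weight_mg = 0,
                          stomach_total_g = 0, fish_total_g = f$mass_g))
      }
      n_items <- 1L + stats::rpois(1, max(pr$items_mean[1] - 1, 0))
      taxa <- sample(pr$prey_taxon, n_items, replace = TRUE,
                     prob = pr$prob)
      wts <- vapply(taxa, function(tx) {
        m <- pr$weight_mean_mg[pr$prey_taxon == tx]
        s <- pr$weight_sd_mg[pr$prey_taxon == tx]
        if (s == 0) return(m)
        sdlog <- sqrt(log(1 + (s / m)^2))
        stats::rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
      }, numeric(1))
      agg_n <- tapply(rep(1L, n_items), taxa, sum)
      agg_w <- tapply(wts, taxa, sum)
      total_g <- sum(wts) / 1000
      data.frame(fish_id = f$fish_id, prey_taxon = names(agg_n),
                 count = as.integer(agg_n), weight_mg = unname(agg_w),
                 stomach_total_g = total_g, fish_total_g = f$mass_g,
                 row.names = NULL)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
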