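#' Standardize continuous predictors
#'
#' Centers each named column and divides by its sample SD (n-1), the
#' scaling used before model fitting so coefficients are comparable and
#' interactions interpretable. Scaling constants are stored so fitted
#' effects can be mapped back to natural units.
#'
#' @param data data.frame of observations.
#' @param vars character vector of columns to scale.
#' @param suffix suffix for the scaled copies (originals are retained).
#' @return `data` with added `<var><suffix>` columns and attribute
#'   `scaling` (data.frame var, center, scale).
#' @export
scale_predictors <- function(data, vars, suffix = "_z") {
  data <- as.data.frame(data)
  stopifnot(all(vars %in% names(data)))
  sc <- data.frame(var = vars, center = NA_real_, scale = NA_real_)
  for (i in seq_along(vars)) {
    x <- data[[vars[i]]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero-variance covariate: ", vars[i])
    sc$center[i] <- mean(x); sc$scale[i] <- s
    data[[paste0(vars[i], suffix)]] <- (x - mean(x)) / s
  }
  attr(data, "scaling") <- sc
  data
}

#' Fit a relative-growth linear mixed model with AR1 errors
#'
#' Fits `fixed` by maximum likelihood (or REML) with a per-fish random
#' structure and optionally a first-order autoregressive residual
#' process within fish, delegating estimation to [nlme::lme()]. The
#' response is expected on the log scale. Returns the Table-2-style
#' coefficient table, AIC, variance components, the AR1 coefficient and
#' marginal/conditional R-squared (variance-partition definition:
#' fixed-effect variance over fixed + random + residual, with the
#' random-effect contribution averaged over the observed design).
#'
#' @param data observation data.frame (one row per fish per increment).
#' @param fixed fixed-effects formula, e.g.
#'   `log_growth ~ size_z + temp_z + class`.
#' @param random random-effects one-sided formula; default
#'   `~ 1 + inc_c | fish_id` (intercept + day-of-life slope). The slope
#'   variable should be the centered increment index.
#' @param ar1 logical; include `corAR1` within fish ordered by
#'   `ar1_time`.
#' @param ar1_time name of the time-order column for AR1 (default
#'   `"increment_index"`).
#' @param group name of the grouping (fish id) column, used by the AR1
#'   form.
#' @param method `"ML"` (required for AIC comparison of fixed effects)
#'   or `"REML"` (final reported fit).
#' @return object of class `growth_fit`: list with `coefficients`
#'   (term, estimate, se, df, t, p), `aic`, `var_components`, `ar1_phi`,
#'   `r2_marginal`, `r2_conditional`, `model` (the lme fit), `converged`.
#'   On optimizer failure returns `converged = FALSE` with the error
#'   message in `diagnostics` and all numerics `NA`.
#' @export
fit_lmm <- function(data, fixed,
                    random = ~ 1 + inc_c | fish_id,
                    ar1 = TRUE, ar1_time = "increment_index",
                    group = "fish_id", method = "ML") {
  data <- as.data.frame(data)
  resp <- all.vars(fixed)[1]
  if (!all(is.finite(data[[resp]]))) stop("non-finite response values")
  corr <- NULL
  if (ar1) {
    corr <- nlme::corAR1(form = stats::as.formula(
      paste0("~ ", ar1_time, " | ", group)))
  }
  fit <- tryCatch(
    nlme::lme(fixed = fixed, random = random, data = data,
              correlation = corr, method = method,
              control = nlme::lmeControl(opt = "optim",
                                         msMaxIter = 200,
                                         returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE,
                          diagnostics = conditionMessage(fit),
                          coefficients = NULL, aic = NA_real_,
                          var_components = NULL, ar1_phi = NA_real_,
                          r2_marginal = NA_real_,
                          r2_conditional = NA_real_, model = NULL),
                     class = "growth_fit"))
  }
  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                      se = tt[, "Std.Error"], df = tt[, "DF"],
                      t = tt[, "t-value"], p = tt[, "p-value"],
                      row.names = NULL)
  vc <- nlme::VarCorr(fit)
  sigma2 <- fit$sigma^2
  # fixed-effect variance over the observed design
  X <- stats::model.matrix(stats::formula(fit), data = data)
  var_f <- stats::var(as.vector(X %*% nlme::fixef(fit)))
  # random-effect variance averaged over the observed Z rows
  re_form <- attr(fit$modelStruct$reStruct[[1]], "formula") %||%
    stats::as.formula(paste("~", deparse(random[[2]][[2]])))
  Z <- stats::model.matrix(re_form, data = data)
  G <- as.matrix(fit$modelStruct$reStruct[[1]]) * sigma2
  var_r <- mean(rowSums((Z %*% G) * Z))
  phi <- NA_real_
  if (ar1 && !is.null(fit$modelStruct$corStruct))
    phi <- unname(stats::coef(fit$modelStruct$corStruct,
                              unconstrained = FALSE)[1])
  tot <- var_f + var_r + sigma2
  structure(list(converged = TRUE, diagnostics = NULL,
                 coefficients = coefs, aic = stats::AIC(fit),
                 var_components = list(random = G, residual = sigma2),
                 ar1_phi = phi,
                 r2_marginal = var_f / tot,
                 r2_conditional = (var_f + var_r) / tot,
                 model = fit, data = data, fixed = fixed,
                 random = random, ar1 = ar1, ar1_time = ar1_time,
                 group = group, method = method),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat("growth_fit: did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("Linear mixed-effects growth model (", x$method, ")\n", sep = "")
  print(x$coefficients, digits = 3)
  cat(sprintf("AIC %.1f  AR1 phi %s  R2m %.3f  R2c %.3f\n", x$aic,
              ifelse(is.na(x$ar1_phi), "-", sprintf("%.2f", x$ar1_phi)),
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Three-step AIC model selection
#'
#' Step 1 chooses the random-effects structure (REML, fixed effects at
#' the global model) between a random intercept and intercept + slope.
#' Step 2 chooses the fixed-effects subset (ML) over all subsets of the
#' global terms (capped at `max_candidates`, always including the
#' intercept-only and global models). Step 3 compares the winner with
#' and without AR1 errors (ML). Ties go to the simpler model; the
#' winner is refit with REML for reporting.
#'
#' @param data observation data.frame.
#' @param response response column name (log growth).
#' @param terms character vector of candidate fixed-effect terms.
#' @param random_candidates list of random formulas, simplest first.
#' @inheritParams fit_lmm
#' @param max_candidates cap on enumerated fixed-effect subsets.
#' @return list: `best` (REML `growth_fit`), `ladder` (data.frame of
#'   every candidate: step, label, aic, converged), `random`, `terms`,
#'   `ar1` chosen.
#' @export
select_model <- function(data, response, terms,
                         random_candidates = list(~ 1 | fish_id,
                                                  ~ 1 + inc_c | fish_id),
                         ar1_time = "increment_index", group = "fish_id",
                         max_candidates = 64L) {
  ladder <- list()
  fml <- function(tms) stats::as.formula(
    paste(response, "~", if (length(tms)) paste(tms, collapse = " + ")
          else "1"))
  # Step 1: random structure under the global fixed model (REML)
  step1 <- lapply(random_candidates, function(r)
    fit_lmm(data, fml(terms), random = r, ar1 = FALSE,
            ar1_time = ar1_time, group = group, method = "REML"))
  aic1 <- vapply(step1, function(f) f$aic, numeric(1))
  for (i in seq_along(step1))
    ladder[[length(ladder) + 1]] <- data.frame(
      step = 1L, label = deparse(random_candidates[[i]]),
      aic = aic1[i], converged = step1[[i]]$converged)
  ok1 <- which(is.finite(aic1))
  if (!length(ok1)) stop("no random-structure candidate converged")
  best_random <- random_candidates[[ok1[which.min(aic1[ok1])]]]

  # Step 2: all fixed-effect subsets (ML)
  subsets <- fixed_subsets(terms, max_candidates)
  step2 <- lapply(subsets, function(tms)
    fit_lmm(data, fml(tms), random = best_random, ar1 = FALSE,
            ar1_time = ar1_time, group = group, method = "ML"))
  aic2 <- vapply(step2, function(f) f$aic, numeric(1))
  sizes <- lengths(subsets)
  for (i in seq_along(step2))
    ladder[[length(ladder) + 1]] <- data.frame(
      step = 2L,
      label = if (sizes[i]) paste(subsets[[i]], collapse = "+") else "1",
      aic = aic2[i], converged = step2[[i]]$converged)
  ok2 <- which(is.finite(aic2))
  if (!length(ok2)) stop("no fixed-effect candidate converged")
  # tie-break toward fewer terms
  ord <- ok2[order(aic2[ok2], sizes[ok2])]
  best_terms <- subsets[[ord[1]]]

  # Step 3: AR1 or not (ML)
  step3 <- lapply(c(FALSE, TRUE), function(a)
    fit_lmm(data, fml(best_terms), random = best_random, ar1 = a,
            ar1_time = ar1_time, group = group, method = "ML"))
  aic3 <- vapply(step3, function(f) f$aic, numeric(1))
  for (i in 1:2)
    ladder[[length(ladder) + 1]] <- data.frame(
      step = 3L, label = c("iid errors", "AR1 errors")[i],
      aic = aic3[i], converged = step3[[i]]$converged)
  ok3 <- which(is.finite(aic3))
  use_ar1 <- (length(ok3) == 2 && aic3[2] < aic3[1]) ||
    identical(ok3, 2L)

  best <- fit_lmm(data, fml(best_terms), random = best_random,
                  ar1 = use_ar1, ar1_time = ar1_time, group = group,
                  method = "REML")
  list(best = best, ladder = do.call(rbind, ladder),
       random = best_random, terms = best_terms, ar1 = use_ar1)
}

fixed_subsets <- function(terms, max_candidates) {
  k <- length(terms)
  if (2^k <= max_candidates) {
    subsets <- lapply(0:(2^k - 1), function(m)
      terms[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  } else {
    # cap: intercept-only, global, and all leave-one-out models
    subsets <- c(list(character(0), terms),
                 lapply(seq_len(k), function(i) terms[-i]))
  }
  subsets
}

#' Marginal means from a fitted growth model
#'
#' Population-level predictions on the response (back-transformed from
#' the log scale) over a grid of focal terms, with non-focal continuous
#' covariates held at their means, non-focal factors averaged with
#' equal weight over their levels, and the increment index fixed (11 by
#' default, the window midpoint).
#'
#' @param fit a converged `growth_fit`.
#' @param focal character vector of focal term names (must appear in
#'   the model frame).
#' @param at optional named list of focal grids; defaults to factor
#'   levels, or 5 quantile points for continuous focal terms.
#' @param increment value at which the increment index is fixed.
#' @param transform back-transform applied to the linear predictor
#'   (default `exp`).
#' @return data.frame: focal columns, `log_mean`, `mean`.
#' @export
marginal_means <- function(fit, focal, at = NULL, increment = 11,
                           transform = exp) {
  stopifnot(inherits(fit, "growth_fit"), fit$converged)
  data <- fit$data
  mf_vars <- all.vars(fit$fixed)[-1]
  missing_focal <- setdiff(focal, mf_vars)
  if (length(missing_focal))
    stop("focal term(s) not in model: ", paste(missing_focal, collapse = ", "))
  grids <- list()
  for (v in focal) {
    if (!is.null(at[[v]])) grids[[v]] <- at[[v]]
    else if (is.factor(data[[v]]) || is.character(data[[v]]))
      grids[[v]] <- sort(unique(as.character(data[[v]])))
    else grids[[v]] <- unname(stats::quantile(data[[v]],
                                              c(.1, .3, .5, .7, .9)))
  }
  focal_grid <- expand.grid(grids, stringsAsFactors = FALSE)
  # reference grid for non-focal terms: factors balanced, numerics at mean
  nonfocal <- setdiff(mf_vars, focal)
  ref <- list()
  for (v in nonfocal) {
    if (is.factor(data[[v]]) || is.character(data[[v]]))
      ref[[v]] <- sort(unique(as.character(data[[v]])))
    else ref[[v]] <- mean(data[[v]])
  }
  ref_grid <- if (length(ref)) expand.grid(ref, stringsAsFactors = FALSE)
  else data.frame(.dummy = 1)
  inc_vars <- intersect(c(fit$ar1_time, "inc_c"), names(data))
  preds <- vapply(seq_len(nrow(focal_grid)), function(i) {
    newd <- ref_grid[rep(seq_len(nrow(ref_grid)), 1), , drop = FALSE]
    for (v in focal) newd[[v]] <- focal_grid[[v]][i]
    for (v in inc_vars) {
      if (v == "inc_c" && fit$ar1_time %in% names(data)) {
        # inc_c is an affine shift of the increment index; recover the offset
        newd[[v]] <- increment + mean(data$inc_c - data[[fit$ar1_time]])
      } else {
        newd[[v]] <- increment
      }
    }
    # factor columns must carry the fit's levels
    for (v in mf_vars) {
      if (is.factor(data[[v]]))
        newd[[v]] <- factor(newd[[v]], levels = levels(data[[v]]))
    }
    mean(stats::predict(fit$model, newdata = newd, level = 0))
  }, numeric(1))
  out <- focal_grid
  out$log_mean <- preds
  out$mean <- transform(preds)
  out
}
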