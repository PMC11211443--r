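#' Default end-to-end pipeline configuration
#'
#' A self-contained synthetic scenario covering a multi-year study:
#' a 30-year baseline temperature record with heatwave-forced years,
#' cohorts sampled in July and August across the three heatwave
#' classes, class-specific diets, and the projection stage. Every
#' default is a stated property of the emulated study system; the
#' configuration is data, so callers override fields rather than
#' editing code.
#'
#' @param seed root seed from which all stage seeds are derived.
#' @return nested list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  sampling <- expand.grid(year = 2006:2019, month = c(7L, 8L))
  sampling$class <- year_class_label(sampling$year)
  sampling$n_fish <- ifelse(sampling$class == "Heatwave", 12L, 30L)
  sampling$start_length_mean <- ifelse(sampling$month == 7L, 45, 65) +
    ifelse(sampling$class == "Heatwave", 8, 0)
  sampling$start_length_sd <- 4
  anomalies <- data.frame(
    start_date = as.Date(c("2014-05-01", "2015-05-01", "2016-05-01",
                           "2019-05-01")),
    duration_days = 170L, intensity_c = 2.5)
  taxa <- c("mysid", "calanoid", "gammarid", "harpacticoid", "caprellid")
  profs <- expand.grid(class = c("Before", "Heatwave", "Between"),
                       month = c(7L, 8L), prey_taxon = taxa,
                       stringsAsFactors = FALSE)
  pmap <- list(Before = c(.10, .45, .25, .15, .05),
               Heatwave = c(.55, .20, .10, .05, .10),
               Between = c(.20, .30, .20, .10, .20))
  profs$prob <- unlist(lapply(seq_len(nrow(profs)), function(i)
    pmap[[profs$class[i]]][match(profs$prey_taxon[i], taxa)]))
  profs$weight_mean_mg <- c(mysid = 12, calanoid = 0.5, gammarid = 4,
                            harpacticoid = 0.2, caprellid = 3)[profs$prey_taxon]
  profs$weight_sd_mg <- profs$weight_mean_mg * 0.5
  profs$empty_probability <- 0.023
  profs$items_mean <- 8
  list(seed = as.integer(seed),
       temperature = list(start_date = "1983-01-01",
                          end_date = "2019-12-31", mean_annual = 8,
                          seasonal_amplitude = 4, phase_day = 227,
                          ar1_phi = 0.8, noise_sd = 0.6,
                          anomalies = anomalies),
       mhw = list(baseline = c(1983L, 2012L), min_duration = 5L,
                  max_gap = 2L, day_threshold = 90L,
                  years = 2006:2019),
       cohort = list(sampling = sampling),
       diet = profs,
       growth = list(window = 21L, psiri_threshold = 3.5),
       projection = list(days = 40L, survival_mode = "none",
                         q_survive = 1))
}

year_class_label <- function(year) {
  ifelse(year %in% c(2014:2016, 2019), "Heatwave",
         ifelse(year %in% 2017:2018, "Between", "Before"))
}

#' Run the full nursery pipeline
#'
#' Executes the stages in dependency order - simulate (or ingest) ->
#' MHW detection -> otolith back-calculation -> diet -> condition ->
#' community -> growth models -> projection - writing each stage's
#' outputs under `outdir` together with a JSON run manifest recording
#' the seeds and stage status. Any stage failure halts with an error
#' naming the stage.
#'
#' @param config configuration list, see [default_pipeline_config()];
#'   alternatively `config$inputs` may name existing CSVs for the four
#'   tables instead of the simulate block.
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run (default all).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = tempfile("nursery_run_"),
                         stages = c("simulate", "mhw", "otolith", "diet",
                                    "condition", "community", "growth",
                                    "project")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    if (!name %in% stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate / ingest -------------------------------------------------
  if ("simulate" %in% stages && is.null(config$inputs)) {
    stage("simulate", {
      tsc <- do.call(temperature_scenario,
                     c(config$temperature,
                       list(seed = derive_seed(config$seed, "temperature"))))
      res$temperature <- generate_temperature(tsc)
      csc <- do.call(cohort_scenario,
                     c(config$cohort, list(seed = config$seed)))
      cohort <- generate_cohort(csc, res$temperature)
      res$fish <- cohort$fish
      res$otolith <- cohort$otolith
      res$stomach <- generate_diets(res$fish, diet_profile(config$diet),
                                     seed = config$seed)
      write_table_csv(res$temperature, file.path(outdir, "temperature.csv"))
      write_table_csv(res$fish, file.path(outdir, "fish.csv"))
      write_table_csv(res$otolith, file.path(outdir, "otolith.csv"))
      write_table_csv(res$stomach, file.path(outdir, "stomach.csv"))
    })
  } else if (!is.null(config$inputs)) {
    res$temperature <- read_table_csv(config$inputs$temperature,
                                      "temperature")
    res$fish <- read_table_csv(config$inputs$fish, "fish")
    res$otolith <- read_table_csv(config$inputs$otolith, "otolith")
    res$stomach <- read_table_csv(config$inputs$stomach, "stomach")
  }

  # --- marine heatwaves --------------------------------------------------
  stage("mhw", {
    clim <- build_climatology(res$temperature, config$mhw$baseline)
    ev <- detect_events(res$temperature, clim,
                        min_duration = config$mhw$min_duration,
                        max_gap = config$mhw$max_gap)
    yc <- classify_years(ev, config$mhw$years,
                         day_threshold = config$mhw$day_threshold)
    res$climatology <- clim; res$events <- ev; res$year_classes <- yc
    write_table_csv(ev, file.path(outdir, "events.csv"))
    write_table_csv(yc, file.path(outdir, "classes.csv"))
  })

  # --- otolith growth ----------------------------------------------------
  stage("otolith", {
    res$growth <- growth_tracks(res$otolith, res$fish,
                                 window = config$growth$window)
    write_table_csv(res$growth, file.path(outdir, "growth.csv"))
  })

  # --- diet --------------------------------------------------------------
  stage("diet", {
    st <- res$stomach[!is.na(res$stomach$prey_taxon), ]
    grp <- apply_grouping_threshold(st, config$growth$psiri_threshold)
    res$diet_composition <- grp$composition
    res$diet_matrix <- psiri_matrix(st, grp$grouping)
    empties <- !res$fish$fish_id %in% st$fish_id
    res$empty_summary <- empty_stomach_summary(
      res$fish$fish_id, empties,
      strata = res$fish[c("month", "class")])
    write_table_csv(grp$composition,
                    file.path(outdir, "diet_composition.csv"))
    utils::write.csv(res$diet_matrix,
                     file.path(outdir, "diet_matrix.csv"))
  })

  # --- condition / abundance --------------------------------------------
  stage("condition", {
    hauls <- stats::aggregate(
      cbind(n_cod = fish_id) ~ year + month + site + haul,
      data = transform(res$fish, fish_id = 1L), FUN = sum)
    res$cpue <- cpue(hauls)
    res$lw <- lw_condition(res$fish)
    res$hsi <- hsi(res$fish$liver_g, res$fish$mass_g)
    res$min_length <- min_length_by_year(res$fish)
    res$pct_change <- percent_change_july_august(res$fish)
    write_table_csv(res$cpue, file.path(outdir, "cpue.csv"))
    jsonlite::write_json(
      list(lw = res$lw[c("intercept", "slope", "adj_r_squared")],
           pct_change = res$pct_change$by_class),
      file.path(outdir, "summaries.json"), auto_unbox = TRUE, digits = NA)
  })

  # --- community ---------------------------------------------------------
  stage("community", {
    labels <- res$fish$class[match(rownames(res$diet_matrix),
                                   res$fish$fish_id)]
    keep <- table(labels)[labels] >= 2
    d <- bray_curtis(res$diet_matrix[keep, , drop = FALSE])
    res$mrpp <- mrpp(d, labels[keep], n_perm = 199,
                      seed = derive_seed(config$seed, "community"))
    res$isa <- indicator_species(res$diet_matrix[keep, , drop = FALSE],
                                  labels[keep], n_perm = 199,
                                  seed = derive_seed(config$seed,
                                                     "community"))
    jsonlite::write_json(res$mrpp[c("A", "observed_delta",
                                    "expected_delta", "p_value")],
                         file.path(outdir, "mrpp.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # --- growth models -----------------------------------------------------
  stage("growth", {
    obs <- merge(res$growth, res$fish[c("fish_id", "class", "year",
                                        "month")], by = "fish_id")
    obs$log_growth <- log(pmax(obs$rel_growth, 1e-8))
    obs$class <- factor(obs$class,
                        levels = c("Before", "Between", "Heatwave"))
    obs <- scale_predictors(obs, "length_mm")
    obs$inc_c <- obs$increment_index - 11
    fit <- fit_lmm(obs[obs$month == 7L, ],
                   log_growth ~ length_mm_z + class)
    res$growth_fit_july <- fit
    if (fit$converged)
      write_table_csv(fit$coefficients,
                      file.path(outdir, "coefficients.csv"))
  })

  # --- projection --------------------------------------------------------
  stage("project", {
    jul <- res$fish[res$fish$month == 7L, ]
    aug <- res$fish[res$fish$month == 8L, ]
    gyr <- stats::aggregate(
      rel_growth ~ year,
      data = merge(res$growth,
                   res$fish[res$fish$month == 7L, c("fish_id", "year")],
                   by = "fish_id"),
      FUN = mean)
    names(gyr)[2] <- "mean_growth"
    pred <- predict_august_sizes(jul, gyr,
                                 days = config$projection$days)
    res$projection <- compare_predicted_observed(pred, aug)
    hw_pred <- pred$predicted_aug_mm[pred$class == "Heatwave"]
    hw_obs <- aug$sl_mm[aug$class == "Heatwave"]
    if (length(hw_pred) >= 2 && length(hw_obs) >= 1)
      res$q_star <- survival_quantile_search(hw_pred, mean(hw_obs),
                                              observed_ci = ci95(hw_obs))
    write_table_csv(pred, file.path(outdir, "projection.csv"))
    if (!is.null(res$q_star))
      write_table_csv(res$q_star$curve,
                      file.path(outdir, "quantile_curve.csv"))
  })

  manifest <- list(package_version = as.character(
    utils::packageVersion("codnursery")),
    seed = config$seed, stages = stages,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the installed `nursery` script:
#' `simulate` (write the four synthetic tables), `validate` (schema
#' report), `run-all` (full pipeline). Arguments: `--seed`, `--outdir`,
#' plus `--temps/--fish/--otolith/--stomach` for `validate`.
#'
#' @param args character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return exit status, invisibly.
#' @export
nursery_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: nursery <simulate|validate|run-all> [--seed N]",
        "[--outdir DIR] [--temps F --fish F --otolith F --stomach F]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  outdir <- opt("outdir", "nursery_out")
  status <- 0L
  if (cmd == "simulate") {
    run_pipeline(default_pipeline_config(seed), outdir,
                 stages = "simulate")
    cat("wrote synthetic tables to ", outdir, "\n", sep = "")
  } else if (cmd == "validate") {
    paths <- Filter(Negate(is.null),
                    list(temperature = opt("temps"), fish = opt("fish"),
                         otolith = opt("otolith"),
                         stomach = opt("stomach")))
    rep <- validate_tables(paths)
    if (nrow(rep)) {
      utils::write.csv(rep, stdout(), row.names = FALSE)
      status <- 1L
    } else cat("all tables valid\n")
  } else if (cmd == "run-all") {
    run_pipeline(default_pipeline_config(seed), outdir)
    cat("pipeline complete: ", outdir, "\n", sep = "")
  } else {
    cat("unknown subcommand: ", cmd, "\n", sep = "")
    status <- 1L
  }
  invisible(status)
}
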