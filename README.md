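# codnursery

Tools for asking whether a coastal nursery still does its job for
age-0 fish when the ocean runs hot. During marine heatwaves (MHWs),
late-summer samples of juvenile gadids can be dominated by a handful of
large "super survivors": fish that are bigger than their measured
growth rates can explain, consistent with size-selective mortality
rather than temperature-accelerated growth. `codnursery` packages the
full analysis chain needed to test that hypothesis — from a raw daily
temperature logger series and otolith increment reads to a
survival-quantile estimate — together with a synthetic-data module that
generates every input table with known truth, so each stage is testable
without any field data.

## What it computes

- **MHW detection** — day-of-year climatology (11-day pooling window,
  31-day smoothing) with a 90th-percentile threshold; events are runs of
  ≥ 5 days above threshold, gap-joined across ≤ 2 cool days, with
  cumulative intensity (°C·days) and Moderate/Strong/Severe/Extreme
  categories from integer multiples of the threshold–climatology gap;
  years binned into Before / Heatwave / Between classes.
- **Otolith back-calculation** — Biological Intercept model,
  `L_a = L_c + (O_a − O_c)(L_c − L0)/(O_c − O0)` with L0 = 3.9 mm,
  O0 = 8.3 µm, and daily relative growth `g_t = (L_t − L_{t−1})/L_{t−1}`
  (mm/mm/day) over the final 21 pre-capture days.
- **Diet** — Prey-Specific Index of Relative Importance,
  `%PSIRI_i = %FO_i (%PN_i + %PW_i)/200` (sums to 100 across taxa),
  stomach fullness, a 3.5 % minor-taxon grouping rule, and empty-stomach
  summaries.
- **Condition & abundance** — CPUE per seine haul, hepatosomatic index,
  pooled log-linear length–weight residuals
  (`ln W = a + b ln SL`), yearly minimum-length models, and
  July→August percent-change summaries.
- **Community comparison** — Bray–Curtis distances, MRPP with the
  chance-corrected agreement statistic *A*, and Dufrêne–Legendre
  indicator species analysis with Monte-Carlo significance.
- **Growth models** — linear mixed-effects models of log relative
  growth (fish-level random intercept, day-of-life random slope, AR1
  residuals via `nlme`), standardized covariates, a three-step AIC
  structure search, and back-transformed marginal means at the window
  midpoint (increment 11).
- **Size projection** — July fish compounded forward
  `L_pred = L_c (1 + ḡ)^d` over the inter-sampling interval
  (default 40 d), predicted-vs-observed August comparison, and a
  survival-quantile search: the largest fraction *q* whose top-*q*
  predicted mean matches the observed August mean, plus a
  10,000-individual simulated-population version.

## Worked example

```r
library(codnursery)

## back-calculate daily length from otolith radii (µm) at capture 60 mm
back_calculate_lengths(c(300, 450, 600), 600, 60, backcalc_params())
#> [1] 31.56 45.78 60.00

## growth-model parameter recovery on synthetic observations
obs <- simulate_growth_observations(n_fish = 150, seed = 42)
fit_lmm(obs, log_growth ~ size_z + temp_z + class)
#>           term estimate      se   df       t         p
#> 1  (Intercept)  -4.3954 0.03612 2999 -121.69  0.00e+00
#> 2       size_z  -0.1346 0.02337  146   -5.76  4.83e-08
#> 3       temp_z  -0.1048 0.00464 2999  -22.61 1.23e-104
#> 4 classBetween  -0.0131 0.05473  146   -0.24  8.11e-01
#> 5  classDuring   0.1223 0.05038  146    2.43  1.64e-02
#> AIC -840.5  AR1 phi 0.33  R2m 0.208  R2c 0.701

## what fraction of July fish must have survived for predictions to
## match an observed August mean of 95 mm?
survival_quantile_search(c(70, 80, 90, 100), 95)$q_star
#> [1] 0.5
```

The recovery fit above was simulated from the study-system defaults
(growth intercept −4.43, size −0.12, temperature −0.11, During-MHW
+0.15 on the log scale): every generating coefficient is inside its
95 % CI, and the variance partition (marginal R² 0.208, conditional
0.701) matches the regime the defaults were derived for. `q* = 0.5`
reads: the observed mean is what you would see if only the largest half
of the cohort had survived.

A full synthetic study — temperature record, MHW classification,
cohorts, otoliths, diets, models, projection — runs end to end with

```r
res <- run_pipeline(default_pipeline_config(seed = 1), outdir = "run1")
```

or from the shell via the installed CLI script
(`inst/scripts/nursery simulate|validate|run-all --seed N --outdir DIR`).

## Layout

- `R/` — implementation, one file per pipeline stage
- `tests/testthat/` — unit, property and acceptance suites
  (`test-acceptance.R` holds the acceptance criteria)
- `vignettes/nursery-heatwave-methods.Rmd` — the methods notes:
  model assumptions, generator realism, numerical choices
- `inst/extdata/` — small text fixtures (reference year classes)
- `scripts/acceptance.R` — the acceptance report
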