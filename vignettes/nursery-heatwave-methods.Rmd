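---
title: "Methods: nursery function under marine heatwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nursery function under marine heatwaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codnursery)
```

This note documents the models behind `codnursery`, the assumptions
they carry, the defaults and why, what the synthetic-data generator
does and does not emulate, and the numerical choices that pin down
reproducibility. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## The scientific question

Shallow coastal habitats act as nurseries for age-0 fish: places to
forage, grow and avoid predators through the first summer. A nursery
that functions well supports a high biomass of *small* individuals.
During marine heatwaves the late-summer sample can instead be a small
number of unusually large fish. Two mechanisms can produce that
pattern: temperature-accelerated growth, or size-selective mortality
that removes the small fish. The package's pipeline separates them by
measuring growth directly (daily otolith increments), projecting the
early-summer cohort forward under measured growth, and asking what
fraction of the cohort must have survived for the projection to match
the late-summer observation.

## Marine heatwave detection

The detector re-implements the standard climatology / 90th-percentile
definition rather than calling an existing detection package, so every
rule is explicit and testable:

* **Climatology.** For each civil day of year (365 slots; Feb 29
  observations pool with Feb 28), all baseline temperatures within ± 5
  days of the slot are pooled across years; the slot's mean and 90th
  percentile are smoothed with a 31-day circular moving average. Feb 29
  gets the mean of its neighbours. The baseline defaults to 1983–2012,
  the first 30 complete years of the kind of logger series the package
  targets; it is an argument, not a constant.
* **Events.** Maximal runs of days strictly above the threshold lasting
  ≥ 5 days; two qualifying runs separated by ≤ 2 below-threshold days
  merge. Gap days count toward duration but not toward cumulative
  intensity, which sums daily (temperature − climatological mean) over
  above-threshold days only — this keeps cumulative intensity
  non-negative.
* **Categories.** The peak anomaly in multiples of the local
  (threshold − mean) gap: 1 Moderate, 2 Strong, 3 Severe, ≥ 4 Extreme.
  On a degenerate climatology (threshold = mean, e.g. a constant
  baseline) categorisation rejects; event *detection* still succeeds
  and reports an `NA` category with a warning, because the flat-baseline
  case is a legitimate limiting test of the detector itself.
* **Year classes.** A year with ≥ 90 event days (about a quarter of a
  year; the motivating MHW years average near 270) is `Heatwave`;
  non-heatwave years after the first heatwave year are `Between`;
  earlier years are `Before`. The published 2006–2019 binning ships as
  a text fixture for validation only.

Two properties worth knowing: the climatology is invariant to permuting
baseline years (pooling is by day of year), and detection is invariant
to a uniform temperature shift when the climatology is rebuilt — both
are asserted in the test suite. On a *noise-free* seasonal cycle the
percentile definition flags a few days around the seasonal peak every
year (the centre of a window is its maximum there); this is a property
of the definition, not a bug, and disappears with realistic noise.

## Otolith back-calculation and relative growth

Daily length at increment *a* follows the Biological Intercept model,
a line through the biological intercept (L0 = 3.9 mm, O0 = 8.3 µm —
published values for the target species) and the capture point:

L_a = L_c + (O_a − O_c)(L_c − L0)/(O_c − O0).

Radii are µm, lengths mm; no implicit conversion anywhere. Relative
growth is the backward difference g_t = (L_t − L_{t−1})/L_{t−1} in
mm/mm/day over the final 21 pre-capture days, increments numbered 1–21
so that 11 is the window midpoint (the reference point for marginal
means). Backward differencing at the window edge is a choice the data
do not dictate; it is configurable in the sense that the full length
vector is returned and any differencing can be applied. Tracks shorter
than the window are kept and flagged rather than dropped, matching the
practice of reading every otolith; replicate-read QC flags (never
discards) fish whose counts differ by more than 10 % relative range.

## Diet composition

With %FO the percent of analysed stomachs containing taxon *i*, and
%PN, %PW the percent-by-number and percent-by-weight *averaged only
over stomachs containing i*, the prey-specific index of relative
importance is %PSIRI_i = %FO_i (%PN_i + %PW_i)/200. The divisor 200
(not 2) is what makes the index sum to exactly 100 across taxa when
all three components are expressed on the 0–100 scale; the identity is
asserted property-style on arbitrary generated tables. PSIRI is
additive under pooling of taxa, which is why merging minor taxa (PSIRI
≤ 3.5 % by default) into "Other" preserves the total. Empty stomachs
and abiotic items are removed before any of this; fullness is
content/(fish − content) with an optional square-root transform applied
at modelling time, never at storage. Whether compositions should be
pooled across years within month or computed per year and averaged is
not decidable from the target description; the package pools, and the
per-stomach matrix lets a caller do otherwise.

## Community comparison

Bray–Curtis dissimilarity feeds MRPP: observed delta is the
group-size-weighted (n_g/Σn_g — the common default; nothing in the
problem dictates the weights) mean within-group distance, the expected
delta is the permutation mean, A = 1 − observed/expected, and the
p-value is the add-one tail including ties. Note the tie point: with
perfectly separated groups, permutations that happen to reproduce the
grouping also reach delta = 0, so p is larger than 1/(n_perm + 1) by
the group-preserving share. Indicator values are
100 × specificity × fidelity with a Monte-Carlo test on each taxon's
maximum over groups. NMS ordination is deliberately out of scope; axis
scores from any standard multidimensional-scaling routine (3-d,
Bray–Curtis) enter the growth models as a plain covariate column.

## Growth mixed models

The response is log daily relative growth. Continuous covariates are
standardized ((x − mean)/SD, n−1 convention) for comparability and
convergence; scaling constants are stored for back-transformation. The
model has a per-fish random intercept, a random day-of-life slope (the
centered increment index stands in for age, which is not observed
directly), and an AR1 residual process within fish. Estimation
delegates to `nlme::lme` — the contract is the returned quantities:
Table-style coefficients with SEs, df, t and p; AIC; variance
components; the AR1 coefficient; and marginal/conditional R² by the
variance-partition definition with the random-effect contribution
averaged over the observed design. Structure selection follows the
conventional three steps — random structure under REML at the global
fixed model, fixed-effect subsets under ML (full enumeration, capped),
error structure (AR1 or iid) under ML — with ties broken toward the
simpler model and the winner refit with REML. Marginal means are
population-level predictions over a focal grid, non-focal numerics at
their means, non-focal factors averaged with equal weight, increment
fixed at 11, back-transformed with exp; in a class-only model the
ratio of two marginal means is exactly e^coefficient, which the tests
use as a closed-form oracle.

Degrees of freedom are `nlme`'s inner–outer allocation, which is also
what produces the characteristic pattern of thousands of denominator
df for within-fish covariates (temperature) and ~n_fish df for
between-fish covariates (size, class); Satterthwaite corrections are
deliberately not attempted.

## Size projection and the survival quantile

Mean July relative growth ḡ (mm/mm/day) is dimensionally a daily
proportional increment, so the only self-consistent way to "sum" it
over the d ≈ 40 days between sampling occasions is multiplicative
compounding, L_pred = L_c(1 + ḡ)^d; the additive reading is
implemented as a documented alternative. The survival quantile q* is
the largest q whose top-q predicted mean is at least the observed
August mean — computed over the empirical grid 1/n…1 plus the landmark
quantiles {0.15, 0.25}, ties toward larger q (conservative survival),
with the whole q → top-q-mean curve returned and checked monotone
non-increasing on every call. Both a mean-matching and a CI-coverage
reading of "aligned" are reported. The simulated-population version
draws truncated-normal (floor 20 mm — lengths are positive) populations
of 10,000, samples at the field n, and reuses the same search; its
closed-form oracle is E[top-q of N(µ,σ)] = µ + σφ(Φ⁻¹(1−q))/q.

## The synthetic-data generator: what it emulates, what it does not

The generator is first-class, tested code, and its defaults are the
stated study conditions, chosen once:

* **Temperature**: seasonal sinusoid (mean 8 °C, amplitude 4 °C,
  maximum mid-August) plus stationary AR1 noise (φ = 0.8, SD 0.6 °C) —
  a plausible subarctic nearshore logger — with additive anomaly blocks
  for heatwave forcing.
* **Growth**: daily log relative growth = fixed effects (intercept
  −4.43, size −0.12, temperature −0.11, Between +0.07, During +0.15 on
  standardized covariates) + fish intercept (SD 0.25) + day-of-life
  slope (SD 0.01) + stationary AR1 residual (SD 0.20, φ = 0.3). The
  variance components were derived once from the reference model's
  printed standard errors and variance partition (marginal R² ≈ 0.21,
  conditional ≈ 0.69) and then frozen; a 150-fish simulation
  reproduces both the SE magnitudes and the R² partition.
* **Lengths** compound multiplicatively, L_{t+1} = L_t(1 + g_t), the
  definition of a mm/mm/day rate. AR1 streams start from their
  stationary distribution so 21-day windows carry no burn-in artifact.
* **Otoliths**: the capture radius follows a configurable linear
  radius–length relation (the field noise structure of that relation is
  unknown, so it is configuration, not an asserted value); increment
  radii are constructed by exactly inverting the Biological Intercept
  line, which guarantees the back-calculation round-trips to numerical
  precision — asserted at < 1e−9 mm.
* **Mass** follows ln W = −11.83 + 3.07 ln SL with lognormal noise
  (SD 0.22, sized for an adjusted R² near 0.93); liver mass comes from
  a truncated-normal hepatosomatic index; diets are per-(class, month)
  multinomial mixtures with lognormal item weights (strictly positive,
  right-skewed) and a stated empty-stomach probability.

Not emulated: spatial structure beyond site/haul labels, tidal
sampling constraints, gear selectivity, immigration/emigration, otolith
reading error, and within-summer arrival pulses. A green end-to-end
test therefore establishes that the *pipeline arithmetic and inference
machinery* behave as specified under a known data-generating process —
not that the field system satisfies the generator's assumptions.

One generator property matters for interpretation: July capture length
is itself the integral of the fish's growth, so size at capture and
growth rate are positively correlated across fish. A survival
experiment that grows survivors at their *own* rates therefore
overshoots a common-rate projection, and the survival-quantile check is
instead run under the mechanism actually being probed — the largest
fish grow to their predicted (common-rate) sizes — which recovers the
truncation fraction exactly. For parameter-recovery experiments the
same endogeneity argues for the dedicated exogenous-design simulator
(`simulate_growth_observations`), in which covariates do not feed back
on the response.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics
  (`stats::quantile` type 7) — pinned because implementations differ.
* Permutation p-values: add-one rule, tie-inclusive; default 999
  permutations; seeded streams throughout.
* All randomness flows from one root seed through named per-stage
  offsets, so toggling stages leaves the others bit-reproducible; a
  fixed scenario + seed regenerates byte-identical tables.
* Degenerate inputs are rejected loudly with the offending unit named:
  capture radius ≤ O0, non-monotone radii (fish id in the message),
  zero-variance covariates (by name), single-member MRPP groups,
  all-empty stomach sets, liver ≥ body mass, content ≥ fish weight.
* Model fits never throw: a non-convergent `lme` returns a structured
  failure with the optimizer message, and the AIC ladder logs and
  excludes such candidates.
* CSV dialect is pinned (UTF-8, comma, ".", ISO-8601 dates).

## Known limitations

* The AIC ladder's fixed-effect step enumerates subsets of the terms it
  is given; interaction hierarchies must be expressed by the caller.
* Marginal means average non-focal factors with equal weights;
  observed-frequency weighting is not implemented.
* The q* search targets the observed mean (with CI coverage reported
  alongside); it does not propagate uncertainty in ḡ.
* Degrees of freedom are `nlme`'s; small-sample corrected inference is
  out of scope.
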