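---
title: "Quantifying behavioral thermoregulation in aquatic ectotherms"
author: "aquatherm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral thermoregulation in aquatic ectotherms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquatherm)
```

## The problem

Small aquatic ectotherms — newts, small fish, aquatic invertebrates —
equilibrate with the water around them within minutes: the high heat
capacity and conductivity of water make a body temperature different from
the local water temperature physically unattainable. What such animals
*can* do is choose **where** in a thermally stratified water column to
sit. In a shallow pond in early summer the surface may be several degrees
warmer than the bottom, so depth choice is a real thermoregulatory lever.

`aquatherm` quantifies this behavior with the standard index triplet of
thermal ecology, adapted to the water column:

* **Preferred temperature range (T~p~ range).** The interval of body
  temperatures an animal maintains in a cost-free laboratory thermal
  gradient, bounded by the 10th and 90th percentiles of its selected
  temperatures. This is the target the animal is assumed to aim for.
* **Operative temperature (T~e~).** The temperature an inanimate body
  with the animal's physical properties would reach. For a small aquatic
  ectotherm this is simply the water temperature at each depth, so the
  depth-by-time temperature grid of the column is the *null distribution*
  of body temperatures available to a non-thermoregulator.
* **Thermal quality of habitat** \(d_e\): the deviation of (mean) T~e~
  from the T~p~ range — zero when the habitat offers preferred
  temperatures, growing as it becomes thermally worse.
* **Accuracy of thermoregulation** \(d_b\): the deviation of body
  temperature T~b~ from the range, computed the same way.
* **Effectiveness of thermoregulation** \(E = d_e - d_b\): values near
  zero indicate thermoconformity, positive values active
  thermoregulation, negative values active avoidance of the preferred
  range.

Because water temperatures change through the day, all indices are
computed *per individual per hour* and summarized afterwards.

## The analysis chain

1. **Gradient trials → T~p~ ranges** (`estimate_tp_table()`). Occupancy
   records at 10-min intervals are mapped to body temperatures via the
   nominal compartment temperatures (default gradient 8–30 °C in 2 °C
   steps). Individuals inactive or out of the water for more than 90 % of
   their records are excluded (strict inequality: exactly 90 % is
   retained). Percentile boundaries use linear interpolation between
   order statistics — rank position \((n-1)p/100\), i.e.
   `quantile(type = 7)` — the most common convention; the method is
   recorded in the run log because percentile definitions differ across
   software. The species-level range applied to all conspecifics is the
   mean of the individual lower boundaries to the mean of the individual
   upper boundaries.
2. **Logger series → T~e~ profiles** (`build_profile()`, `te_at()`).
   Dataloggers every 5 cm of a 45-cm column at 30-min intervals define a
   depth-by-time grid. Queries off the grid are answered by bilinear
   interpolation (linear in depth at the bracketing times, then linear in
   time); grid points are returned exactly. Hourly analysis instants are
   evaluated by interpolating the 30-min series to the exact clock hour
   rather than averaging the bracketing readings — one continuous
   convention instead of two. A single missing timestep at a depth is
   filled by linear interpolation in time (nearest value at the grid
   boundary); two or more consecutive missing timesteps are an error,
   because bridging them would invent unobserved thermal structure. When
   only some tanks carry loggers, the others inherit the profile of the
   nearest logger-equipped tank (`tank_map`);
   `check_inter_tank_consistency()` verifies that the worst across-tank
   spread stays within 1 °C, the envelope within which this inheritance
   is defensible.
3. **Indices** (`build_index_table()`). T~b~ of each observed animal is
   the water temperature at its occupied depth. Two \(d_e\) conventions
   are provided. The default, `deviation_of_mean`, is the deviation of
   the across-depth *mean* T~e~ from the range. The alternative,
   `mean_of_deviations`, averages the deviation over all available
   depths; it is the form under which an animal occupying uniformly
   random depths has \(\mathbb{E}[d_b] = d_e\) and hence
   \(\mathbb{E}[E] = 0\), which makes it the natural yardstick for
   thermoconformity and the convention used by the conformer-null checks
   in the test suite. Both are reported in output metadata. \(E\) is
   reported in the difference form by default; the historical ratio form
   \(E = d_b/d_e\) is available as printed in the classical description,
   with an undefined flag at \(d_e = 0\) — note that some later authors
   define the ratio index as \(1 - d_b/d_e\), so ratio values should not
   be compared across studies without checking the convention. Negative
   \(E\) values are reported as-is; they are informative (avoidance),
   not errors.
4. **Inference** (`permutation_anova()`, `factorial_permutation()`,
   `bootstrap_ci()`, `variance_explained()`). Index distributions are
   typically non-normal with outliers, so group effects are tested by
   randomization: the observed pseudo-F (between/within mean-square
   ratio) is compared to its distribution under label permutation, with
   the add-one rule \(p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})\) and ties
   counted against the null. The default analysis unit is the
   *individual*: records are collapsed to per-individual means before
   permuting, so repeated measures of the same animal are never treated
   as independent evidence. Record-level permutation is available
   explicitly (and is reported alongside in the pipeline). In the
   two-factor test, main effects use restricted permutation (shuffling
   only within levels of the other factor) and the interaction uses
   residual (Freedman–Lane-style) permutation of the additive-model
   residuals; sums of squares are Type II. Confidence intervals are
   non-parametric percentile bootstrap intervals (default 9999
   replicates). Repeatability of a trait is summarized as
   \(100 \cdot SS_{between~individuals}/SS_{total}\).
5. **Daily trend** (`fit_quadratic_trend()`). Daytime T~e~ and T~b~ rise
   in a curvilinear fashion; the package fits
   \(T = \beta_0 + \beta_1 t + \beta_2 t^2 + \beta_3\,[species]\) by
   ordinary least squares on raw (uncentered) decimal clock hours. This
   is deliberately the *fixed-effects skeleton* of the general linear
   mixed models usually applied to such repeated-measures series: random
   individual intercepts/slopes and variance covariates are out of scope
   here, so the reported standard errors understate between-individual
   uncertainty and should be read accordingly. Coefficient *estimates*
   on noiseless data are exact to numerical precision, and unbiased
   under noise.

## The synthetic-study generator

No raw field or tank data ship with the package, so every stage is
validated against simulated studies with known ground truth
(`sim_config()`, `generate_study()`).

**What it emulates.** A mid-June semi-natural tank study: a 45-cm water
column logged every 5 cm and 30 min; surface temperature following the
quadratic daytime trend \(-17.076 + 4.912\,t - 0.144\,t^2\) (about
17.6 °C at 10:00 rising to a plateau near 24.8 °C around 17:00, the
shape and scale of logged operative temperatures in such settings);
linear vertical stratification of 0.08 °C/cm (3.6 °C surface-to-bottom,
a typical early-summer contrast for sun-exposed shallow tanks); Gaussian
cell noise of 0.3 °C, the order of common logger resolution; a 14-tank
array with loggers in two marginal and one middle tank, per-tank
perturbations of 0.1 °C keeping the array inside the 1 °C consistency
envelope, and every unlogged tank inheriting its nearest logger profile;
hourly observations of each animal between 10:00 and 17:00 on one study
date. The default two-species design contrasts 30 *thermoregulators*
holding a cool preferred range (15.9–19.9 °C, centered on a 17.9 °C
preference) with 26 *thermoconformers* holding a warmer, wider range
(19.2–24.2 °C): the habitat is thermally poor for the cool-preference
species and benign for the warm-preference one, so the regulator should
show positive \(E\) and the conformer \(E \approx 0\). Gradient trials
simulate 15 individuals per species at 10-min intervals with 3
(regulator) and 1 (conformer) fully motionless animals, exercising the
inactivity filter the way real trials do.

**The behavioral rule.** Each hour, a thermoregulator selects — with
probability `effort` (default 0.85, an imperfect but determined
regulator) — the grid depth whose temperature deviates least from its
range, breaking ties toward the *deepest* such depth (thermoregulating
animals in warming columns retreat downward); otherwise, and always for
a conformer, it occupies a uniformly random grid depth. A conformer is
implemented *exactly* as a regulator with `effort = 0`, so the
degenerate equivalence is structural, not statistical. The choice is
memoryless between hours: the pipeline consumes hourly snapshots only,
so movement costs and temporal autocorrelation of position — which real
animals certainly have — are deliberately not modelled. The ground-truth
ledger carries the analytic expectation of \(E\) under the rule
(`effort` × the per-hour gap between mean-of-deviations \(d_e\) and the
best achievable \(d_b\)), against which pipeline output is checked.

**What it does not emulate — and what passing tests therefore show.**
Simulated columns are linearly stratified with independent Gaussian
noise; real columns have nonlinear thermoclines, diel mixing, and
spatially correlated structure. Agents have no memory, no predators, no
feeding, and one study date. Passing recovery tests therefore
demonstrate that the *estimators and tests* do what they claim under
controlled conditions — not that any particular field system satisfies
their assumptions.

## Numerical choices and degenerate inputs

* Interpolated temperatures are always bounded by the four bracketing
  grid values; lattice points are reproduced exactly.
* `estimate_tp_range()` requires at least 10 observations by default; the
  per-individual sample size is always recorded rather than assumed.
* Logger values are used as supplied; the package never re-quantizes
  temperatures to a logger's nominal resolution.
* Zero total variance short-circuits: `permutation_anova()` returns
  \(p = 1\), `variance_explained()` flags the decomposition undefined,
  and a constant-vector `bootstrap_ci()` collapses to the point.
* The ratio form of \(E\) is `NA`-flagged at \(d_e = 0\) rather than
  propagating an infinity.
* All resampling accepts a seed, the pipeline seeds once at entry, and
  reruns with the same seed and inputs are byte-identical.

## Validation problem sizes

The test suite validates the percentile estimator against a brute-force
sort-and-interpolate oracle on 1,000 random vectors (lengths 2–50), the
permutation p-value against exhaustive enumeration on two-group designs
with up to 8 units, type-I error over 500 null datasets at 499
permutations, bootstrap coverage over 500 replicates of normal samples
(n = 30, 999 replicates each), trend recovery over 200 noisy replicates
of 240 observations, and end-to-end strategy recovery on the default
30 + 26 × 8-hour synthetic study. These sizes were chosen to give
Monte-Carlo error comfortably below each check's tolerance.

## A worked example

```{r example, eval = FALSE}
library(aquatherm)
st <- generate_study(dir = "study")        # two-species synthetic study
res <- run_pipeline(list(
  paths = list(loggers = st$files$loggers,
               observations = st$files$observations,
               gradient = st$files$gradient),
  tank_map = as.list(st$tank_map),
  n_perm = 9999, n_boot = 9999, seed = 1))
subset(res$summary, metric == "e_diff_C")
res$tests
```

The regulator species ends with positive mean \(E\) (it keeps its body
temperature below the warming column's mean), the conformer with mean
\(E\) near zero, and the species effect on \(E\) is detected by the
permutation test — the qualitative signature of disparate
thermoregulatory strategies under the same thermal conditions.

## Known limitations

* The trend module's standard errors ignore the repeated-measures
  structure (fixed effects only); use them for description, not
  inference.
* The permutation test's denominator degrees of freedom follow from the
  chosen analysis unit and are reported explicitly; they need not match
  any particular published layout, which may have used different units
  per test.
* The simulator's thermal field is a one-parameter linear gradient; it
  cannot produce inverted or mixed columns except through its noise
  term.
* Depth choices are temporally independent between hours; autocorrelated
  movement would inflate the effective repeated-measures correlation in
  ways the generator cannot probe.
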