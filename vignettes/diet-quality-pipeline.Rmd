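---
title: "Diet-quality scoring and the mother–offspring analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-quality scoring and the mother–offspring analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heicohort)
```

## The scoring model

The Danish Healthy Eating Index summarises adherence to the Danish
food-based dietary guidelines as eight component scores of 0–10 points
each, summed to 0–80. Each component has a zero-point (the intake scoring
0) and a full-point (the intake scoring 10); between them the score is the
linear interpolation `10 (x − x₀)/(x₁₀ − x₀)`, clamped to [0, 10]. Three
components are *adequacy* components (fruits and vegetables, dietary
fibre, fish — more is better up to the full-point); five are *moderation*
components (red meat, saturated fat, sodium, sugar-sweetened beverages,
added sugar — less is better). `hei_components()` prints the cutoffs.

Assumptions worth making explicit:

* **Boundary continuity.** Printed guideline cutoffs mix "≥", "≤" and ">"
  forms; a continuous piecewise-linear score forces the value *at* the
  zero-point to be exactly 0 (sodium at 2.4 g/day scores 0, red meat at
  500 g/week scores 0). The interpolation endpoints, not the inequality
  glyphs, define the function.
* **The halving rule.** The guideline asks that at least half of the
  fruit-and-vegetable total be vegetables. When fruit exceeds vegetables
  the component score is multiplied by 0.5 *after* clamping, so the
  maximum attainable with fruit > vegetables is 5.
* **Absolute intakes.** Scores are computed on absolute intakes, not
  energy-standardised ones, even though guideline quantities are nominally
  phrased per 10 MJ/day. This matters when comparing groups with very
  different energy intakes.
* **Energy percentages.** Saturated fat and added sugar are scored as
  percent of total energy. The default route is gram mass × energy factor
  / total energy, with the Nordic factors (fat and hence SFA 37 kJ/g,
  carbohydrate and hence added sugar 17 kJ/g, protein 17 kJ/g; see
  `hei_energy_factors()`). Intake tables that already carry an E% column
  (`sfa_epct`, `added_sugar_epct`) are used as-is. A doubling of nutrient
  mass and energy together leaves the E% score unchanged.
* **Weekly components.** Fish, red meat and SSB cutoffs are weekly;
  `read_intake_csv()` multiplies columns declared `g/day` by 7. For SSB
  the millilitre and gram scales are treated as equivalent (beverage
  density ≈ 1).
* **Missing fields.** Profiles missing a required field are dropped with
  a warning naming the subjects — never scored as zero, which would
  silently deflate totals.

## The cohort analysis

The primary analysis ranks mother and offspring totals into quartiles of
the analysis sample and estimates the relative risk of the offspring
being in the top quartile, by maternal quartile (Q1 reference), from a
log-linear binomial model. Numerical choices:

* **Quartiles** use the empirical 25th/50th/75th percentiles with the
  linear-interpolation definition (`stats::quantile()` type 7), computed
  on the post-exclusion analysis sample. Ties at a cutpoint go to the
  lower quartile. Re-running on the same scores is bit-identical. All-tied
  inputs raise an error rather than returning arbitrary ranks.
* **Log-binomial fitting.** The binomial likelihood with a log link can
  step outside the parameter space (fitted risks above 1) during IRLS.
  The fit therefore starts from the Poisson solution — for a saturated
  model that *is* the maximum-likelihood estimate — with the intercept
  nudged down if any starting risk reaches 1, and a convergence tolerance
  of 1e-10 so that unadjusted fits agree with closed-form proportion
  ratios to ~1e-10 relative error. If the binomial fit still fails, the
  model is refit as Poisson with an HC0 sandwich variance and flagged
  `fallback_used` — the standard epidemiological fallback for RR
  estimation. An exposure level with zero cases in an unadjusted fit is
  reported as complete separation by name rather than producing an
  infinite estimate.
* **Confidence intervals** are Wald intervals on the log scale
  (±1.96 SE); these reproduce the published intervals recomputed from the
  bundled contingency tables to the printed 2 decimals.
* **Trend test.** The quartile factor is replaced by the within-quartile
  median of the exposure score, entered as one continuous term; the
  two-sided Wald p for that term is the trend p. Medians are computed in
  the analysis sample, not taken from printed group summaries.
* **Adjustment sets.** `model_a_covariates()` is the maternal set (age,
  prepregnancy BMI category, parity, education, lactation, physical
  activity, alcohol, smoking); `model_b_covariates()` adds offspring sex
  and offspring energy-intake quartile, the latter quartiled on the
  analysis sample. Missing covariates are imputed (median for age, mode
  for smoking/activity/parity) except prepregnancy BMI, which keeps an
  explicit `missing` category. No multiple-testing correction is applied
  anywhere; p-values are reported raw and two-sided.
* **Interaction.** The sex-interaction check adds exposure×sex product
  terms and tests them jointly with a Wald chi-square on the (possibly
  robust) covariance.
* **Chi-square tests** in the attrition comparison are uncorrected for
  tables larger than 2×2; Yates correction for 2×2 tables is available
  but off by default. Expected cell counts below 5 attach a warning flag
  to the entry rather than blocking the result.

## The synthetic cohort generator

Real two-generation FFQ data of this kind is not publicly deposited, so
the package ships a generator that emulates the statistical structure the
pipeline assumes, making every stage testable end to end.

* **Joint structure.** Mother and offspring each have a latent
  diet-quality variable; the pair is bivariate normal. Each dietary
  component's rank is a noisy transform of the latent quality (Gaussian
  copula): `u = Φ(λz + √(1−λ²)ε)`, mapped through the component's marginal
  quantile function. Loadings λ are positive for adequacy components,
  negative for moderation components, and near zero for sodium and energy,
  whose observed correlations with the total score are essentially nil in
  cohorts of this kind.
* **Marginals** (`default_margins()`) are lognormal for the skewed
  components (fruit & veg, fish, red meat, SSB, added-sugar E%) with
  median and interquartile range matched to the cohort's printed dietary
  summaries, and zero-truncated normal for the symmetric ones (fibre,
  SFA E%, sodium, energy). E% components are generated on the E% scale and
  converted to gram masses with the subject's own energy intake, so
  scoring reconstructs the generated E% exactly.
* **Correlation calibration.** Clamped piecewise-linear scoring attenuates
  the latent correlation: the correlation of scored totals is close to
  `ρ_latent · c_m · c_o`, where `c` is each margin's correlation between
  scored total and latent quality. The generator estimates `c_m` and `c_o`
  by a pilot simulation (20,000 subjects, drawn inside the seeded stream)
  and inflates the latent correlation accordingly, so that
  `simulate_pairs(rho = 0.22)` yields *scored* totals correlating at
  ≈ 0.22. With the default margins the attenuations are ≈ 0.75 and 0.71,
  giving a latent correlation of ≈ 0.41.
* **Score moments.** The defaults produce totals with mean ≈ 23 and
  SD ≈ 8–9 for both generations — close to, but not exactly, the reference
  moments of 24 (7) and 24 (9); the marginal-matched component intakes,
  not the total-score moments, are the calibrated quantity. The vegetable
  share of the combined fruit-and-vegetable intake is Beta(8, 8), so about
  half of subjects trigger the halving rule, as a marginal-only constraint
  cannot identify the split.
* **Covariates** carry plausible quality gradients (older, better-educated,
  more active, less smoking at higher latent quality), with the low levels
  of item missingness typical of such cohorts (≈ 5% for prepregnancy BMI,
  ≤ 1% elsewhere). An attrition model can mark participation as a function
  of covariates for planted-effect recovery checks.
* **Exclusion presets** (`paper_flow_preset()`: 21,082 pairs; 351
  implausible energies, 1,144 multiple births, 5 offspring aged 15+)
  inject rows that *genuinely violate* the corresponding filter — the
  background energy distribution is clamped to the plausible window so the
  preset alone controls the counts, and `apply_exclusions()` then leaves
  exactly 19,582 rows by filtering, not by reading flags.
* **Determinism.** One seeded RNG stream per run; the same seed produces a
  byte-identical cohort, and the caller's RNG state is restored.

What passing tests on these cohorts do **not** show: the generator's joint
distribution is a modelling choice, not an estimate of any real cohort's
joint intake distribution (printed marginal summaries cannot identify it).
Adjusted-model estimates, real-data correlations and attrition contrasts
are therefore checked only as planted-effect recoveries, not as numeric
reproductions.

## Problem sizes used in the checks

The reference-table refits are exact and instantaneous. Simulation checks
use the full cohort size (19,582 pairs) where a published value is the
comparator — the ten-seed quartile-RR check against the quadrature value
`bvn_quartile_rr(0.22)` = 2.0765, and the end-to-end correlation
recovery — and smaller cohorts (2,000–8,000) for property checks such as
trend-test size (500 null replicates), envelope checks and planted-effect
recoveries, where sampling error, not scale, drives the assertion.

## Known limitations

* The log-binomial fallback covariance (HC0) is consistent but can be
  anti-conservative in very small strata; small strata are flagged by
  `stratified_fit()` rather than suppressed.
* The generator draws covariates conditionally independent given the
  latent quality; real covariate intercorrelations (e.g. education ×
  smoking) are stronger than what the quality gradient alone induces.
* Quartile cutpoints follow one fixed percentile definition; software that
  uses a different quantile type will place a handful of boundary subjects
  differently, which can move third-decimal digits of RRs at cohort scale.
* The variance explained by the maternal score in a bivariate-normal world
  is r² (≈ 5% at r = 0.22); adjusted models on real data can report larger
  shares. The package reports both unadjusted and adjusted R² from
  `continuous_association()` and deliberately does not target any
  particular figure.
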