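---
title: "Constructing and validating a traditional diet score for Costa Rican adolescents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a traditional diet score for Costa Rican adolescents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrad)
library(dplyr)
```

## The score

The Traditional Costa Rican Adolescents Diet (TCRAD) score measures
adherence to a traditional Costa Rican dietary pattern from 3-day food
records. It is a binary adherence index over 14 food groups: legumes,
vegetables, fruits, vegetable oils, dairy and corn tortilla are scored as
healthy, and white rice, red/processed meat, solid fats, desserts/pastries,
sugary drinks, snacks, fast food and refined bread/cookies as unhealthy.
For a healthy component, a participant earns 1 point when their usual
intake (g/day) meets or exceeds the sex-specific median cutoff, and 0
otherwise. Unhealthy components are inversely scored: the point is earned
strictly below the cutoff. At exactly the cutoff a healthy component scores
1 and an unhealthy component 0 — the strict logical inverse; the inverse
tie case is a convention this package fixes explicitly because "inverse
scoring" alone does not determine it. Points sum to a 0–14 total, banded
into low (< 6), moderate (6–7) and high (8–14) categories.
Socioeconomic status is classified from a 0–100 household point score: low
≤ 29, medium 30–84, high ≥ 85. (The package consumes the precomputed
point score; the 12-variable allocation behind it is out of scope.)

Cutoffs can be supplied — the bundled table carries the development
sample's sex-specific medians, so `load_cutoffs()` reproduces the published
scoring — or re-derived from a new cohort's own medians with
`derive_cutoffs()`, which is how such indices are transported between
populations. Provenance is recorded on the scored object either way. A
derived cutoff of 0 (possible for episodically consumed foods such as
tortilla) makes a healthy component a free point; the scorer warns when
that happens rather than silently inflating scores.

## Pre-scoring pipeline

The pipeline order is **exclusion → usual-intake estimation → energy
adjustment → scoring**.

**Energy-outlier exclusion.** Implausible reported energy intakes are
screened per sex: participants whose mean daily energy falls strictly
below that sex's 1st percentile or strictly above its 99th are removed.
Percentiles use linear interpolation between order statistics
(`stats::quantile` type 7, configurable); values exactly equal to a
threshold are retained, a choice this package documents because the verbal
rule ("in the 1st percentile or above the 99th") is ambiguous. Two
consequences of percentile screens are worth knowing: a continuous sample
always has ~2% in its own strict tails, so on clean continuous data the
filter removes about 2% per sex by construction; and contamination above
1% per tail within a sex saturates that tail, so the companion
contamination generator (`inject_energy_outliers()`) stratifies by sex and
splits outliers half upward, half downward. With fewer than 10 participants
of a sex the percentiles are too unstable and that sex is left unfiltered
with a warning.

**Usual-intake estimation.** The default estimator is the person mean over
the available days (1–3; missing days are tolerated and counted). A
one-way shrinkage estimator is also provided:
$u_i = \hat\mu + \lambda_i(\bar x_i - \hat\mu)$ with
$\lambda_i = \hat\sigma^2_b / (\hat\sigma^2_b + \hat\sigma^2_w / k_i)$,
variance components from the person/day method-of-moments decomposition
(negative between-person estimates truncated at 0). This is a deliberately
simple stand-in for full usual-intake modeling such as two-part
measurement-error models: it captures the one property that matters
downstream — pulling noisy short-term means toward the population mean in
proportion to the within/between variance ratio — and is labeled as such.
$\lambda \in [0,1]$ always, so the estimate interpolates between the
individual and population means.

**Energy adjustment (residual method).** Each variable is regressed on
total energy by OLS and replaced by its residual plus the value predicted
at the sample mean energy. Adjusted values therefore keep the variable's
sample mean exactly, are uncorrelated with energy (to numerical
precision), and sit on the original scale. Negative adjusted values can
occur and are retained: scoring and the category-median tables compare
each participant to statistics of the same adjusted distribution, so only
ranks matter. Adjustment applies to both nutrients and food-group intakes,
since the category-median validation table is built on energy-adjusted
component intakes. Whether the published cutoffs were computed on raw or
adjusted intakes is not stated in the source material; the pipeline
exposes both (`score_on = "raw"` or `"adjusted"`, default raw, which is
what median g/day cutoff values most plausibly reflect) and records which
was used.

## The synthetic cohort generator

No participant-level data are deposited for the development study, so the
package ships a generator (`cohort_config()` / `generate_cohort()`) that
emulates the data structure every stage assumes, with the development
sample's published summaries as defaults:

* **Usual intakes** are log-normal per person and component — dietary
  intake distributions are right-skewed, medians are the scoring anchor,
  and the log-normal preserves a configured median under multiplicative
  effects. Anchors default to the development sample's sex-specific
  medians.
* **Stratum effects** are multiplicative and centered on the log scale:
  rural and urban carry half the log rural/urban ratio with opposite
  signs, and SES classes carry −1/0/+1 times a per-component trend. Effect
  sizes default to the log-ratios of the published stratum means (rural ↑
  beans, vegetables, oils, white rice; urban ↑ dairy, solid fats, sugary
  drinks, bread, snacks, fast food; high SES ↑ dairy, sugary drinks,
  bread, fast food and ↓ beans, white rice, oils). Centering keeps the
  population medians on the anchors, so anchor-recovery and stratum-effect
  behavior can be tested simultaneously.
* **Within-person variation** multiplies each day by
  $\exp(\sigma_w \varepsilon - \sigma_w^2/2)$, making the day-level mean
  unbiased for the usual intake; person means then center on a quantity
  whose population median is the anchor. Defaults $\sigma_b = 0.5$,
  $\sigma_w = 0.6$ (log scale) reflect the common finding that day-to-day
  variation in food-group intake is at least as large as between-person
  variation.
* **Energy** is a composition-weighted sum of the day's food groups
  (typical kcal/g densities; oils and solid fats near pure fat) plus a
  700 kcal basal term for foods outside the 14 groups and day-level noise
  (SD 150 kcal), landing mean energy near the study's ~1,940 kcal/day with
  boys above girls.
* **Nutrients** are linear combinations of the day's food groups plus
  noise, with fiber, folate, magnesium and potassium loaded on legumes,
  vegetables and fruits, and saturated fat on solid fats, red meat,
  desserts, snacks and fast food — the sign structure the validation
  battery should recover. Loadings are order-of-magnitude food-composition
  values, not a nutrient database.
* **Sampling defaults**: 804 participants, 36% boys / 64% girls, 50/50
  urban/rural, SES class proportions 32/40/28 with point scores uniform
  within each class band, ages 13–18, 80/20 public/private schools, three
  recorded days labeled weekday/weekday/weekend (the labels carry no
  distributional effect — the design balances them, the model does not).
  Optional per-component zero-inflation (default 0) represents
  never-consumers of episodic foods; no consumption-frequency data exist
  to calibrate it.

All draws come from one stream governed by the single `seed` in the
config; `TrueParameters` (the drawn usual intakes) are returned alongside
the records for parameter-recovery testing.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: school-level clustering and the three-stage
sampling design, seasonal (rainy/dry) effects, misreporting other than the
explicit energy contamination, correlation between food groups beyond what
the shared stratum effects induce, and real nutrient composition.

## Validation battery

`correlate_score_nutrients()` computes Spearman rank correlations
(average ranks for ties, two-tailed p, normal approximation) of each
nutrient with the total score; a constant nutrient is reported as
undefined (`NA`), never 0. `medians_by_category()` gives per-component
median (min–max) within each score category with a Kruskal–Wallis test
across categories and the three pairwise Wilcoxon rank-sum comparisons —
exact p below 20 per group when tie-free, otherwise the normal
approximation with tie correction and no continuity correction. No
multiplicity correction is applied by default (matching the source
analysis's apparent practice); Bonferroni is available.
`compare_by_strata()` summarises the score and components by sex, area,
SES class, age group (12–15 / 16–19) and school type with Kruskal–Wallis
tests; `compare_characteristics()` does the sample-characterization
chi-square (no continuity correction by default) and t-tests;
`category_proportions()` produces the row-normalized low/moderate/high
percentages per stratum. All tests are two-tailed at α = 0.05, and stars
follow the \*, \*\*, \*\*\* convention at 0.05/0.01/0.001.

## Worked example

```{r example}
cfg <- cohort_config(n = 400, seed = 7)
sim <- generate_cohort(cfg)
excl <- exclude_energy_outliers(sim$records, sim$participants)
usual <- estimate_usual_intake(excl$records)
scored <- score_cohort(usual, sim$participants, cutoffs = "derive")
glance(scored)
category_proportions(scored, "area")
```

Scoring a cohort against its own derived medians centers the total near 7
(each component contributes ~0.5 points by the median property), and the
default stratum effects reproduce the published direction: rural
adolescents hold the high-score category more often than urban ones.

## Numerical and design choices

* Percentile definition type 7 and the retain-at-threshold tie rule are
  configurable; both choices are stated above.
* The category and SES band rules are data
  (`score_category_rule()`, `ses_rule()`), not code, so alternate indices
  can re-band without touching the scorer.
* Component order never affects totals; scoring is a pure fold over the
  index definition.
* Empty cohorts score to empty results without error; a missing component
  intake is an error naming the component — no imputation.
* The source text describes the score range as 0–14 while one of its
  summary tables is headed 0–13 and one passage counts "seven" unhealthy
  components while listing eight; this package follows the 14-component,
  0–14 construction throughout.
* Problem sizes in the test suite (e.g. median-property checks at
  n = 5,000, sign-pattern recovery over 100 cohorts of n = 2,000) were
  chosen as the smallest sizes at which the properties under test are
  stable.

## Limitations

The package validates the *construction* of the score, not its association
with health outcomes; correlations obtained on synthetic cohorts inherit
the generator's loading matrix and say nothing about real nutrient
composition. The shrinkage estimator ignores episodic consumption
(two-part structure) and covariates. Survey weights, BMI/anthropometry,
and regression modeling of the score on covariates are out of scope.
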