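---
title: "Weighting- and ranking-based hybrid feature selection: models and methods"
author: "wrhfs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighting- and ranking-based hybrid feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrhfs)
```

## The problem

Clinical risk detection from routine laboratory panels faces a feature
selection problem: dozens of blood-test and demographic variables are
available, individual filter statistics disagree about which matter, and a
parsimonious panel is wanted for deployment. WRHFS (weighting- and
ranking-based hybrid feature selection) addresses this for binary outcomes
(here: ischemic-stroke risk, label 1 = case, 2 = control) by fusing several
filter scorers through a classifier-guided voting scheme rather than
trusting any single statistic.

## The pipeline

The data object is a `FeatureTable`: a complete numeric matrix of p
features over n subjects with a binary label. Completeness is a hard
precondition — records with missing values are excluded at ingestion, never
imputed, mirroring the design of the original stroke application.

**Filter stage.** Six candidate scorers (`scoreStd`, `scorePearson`,
`scoreFisher`, `scoreInfoGain`, `scoreRelief`, `scoreChi2`) each produce a
raw score per feature, a min-max normalisation $s_m \in [0,1]$, and a
descending ranking (ties broken by canonical column order). All scorers
that operate on feature values do so *after* min-max scaling each feature
to $[0,1]$: the reference study's printed standard deviations (maximum
0.21) are only consistent with unit-interval features, and scaling makes
spread-based scores comparable across clinical units (IU/L, mmol/L, years,
...). Variances are population (1/n) variances throughout.

**Wrapper stage.** For a given ranking, `prefixAccuracyCurve()` evaluates
the top-$i$ features for $i = 1..p$ with a cross-validated RBF support
vector machine, re-tuned per prefix by exhaustive grid search over the
penalty $C$ and kernel bandwidth $q$ (kernel
$\exp(-\lVert u-v\rVert^2/2q^2)$). The "backward searching strategy" of the
original description is operationalised as this incremental prefix
evaluation in descending rank order: the published accuracy column rises
feature by feature and its contribution column equals consecutive
differences (e.g. $67.9 - 61.6 = 6.3$), which is consistent with prefix
growth and not with backward elimination. The raw contribution of the
feature added at position $i \ge 2$ is the accuracy first difference; the
top-ranked feature's raw contribution is undefined and its *normalized*
contribution is assigned 1.00, copying the convention visible in the
published per-filter table. The remaining raw contributions are min-max
mapped to $[0,1]$.

**Voting and assessment.** With three active filter models the engine forms

* $W = \sum_m s_m$, the weight-sum vector (row sums of the score matrix);
* $C$, the $p \times 3$ matrix of normalized contributions $c_m$;
* $D$, the column-wise cumulative sums of $c_m$ in each model's rank order;
* $P = W \times D$, one effectiveness coefficient per active model;
* $W_r = C \times P$, the fused feature weights.

A note on notation: the source description uses one symbol for both the
normalized filter scores and the wrapper contributions. The printed tables
disambiguate — the weight-sum column equals row sums of the *score*
columns, while the cumulative block equals cumulative *contributions* — and
this reconciled reading, which reproduces every printed quantity (the
coefficients 52/61/63, the fused weights with Age ≈ 52+61+63 = 176), is the
only pipeline implemented. A literal reading cannot reproduce any printed
table.

The tournament (`tournament()`) assesses all candidate filters three at a
time: compute $P$, record coefficients, replace the weakest active model by
the next unused candidate, repeat until the candidate set is exhausted, and
keep the three models with the largest recorded coefficients. Because $W$
and $D$ depend on which trio is active, a model assessed in several rounds
keeps its largest coefficient. The default initialisation is deterministic
(first three of the catalog `std, pearson, fisher, infogain, relief,
chi2`); a seeded random initial trio is available.

**Selection.** Features are ranked by $W_r$; the selected panel is the
minimal prefix whose cumulative share of the total weight *strictly*
exceeds 50% ("more than 50%"). On the published weights this selects 9 of
28 features.

**Risk index.** The synthetic value of a subject is
$SV = \sum_f w^{01}_f \, x_f$ over the selected features, with $w^{01}$ the
min-max-normalized weights (top feature coefficient 1) and $x_f$ raw
clinical values. `strokeRiskModel()` exposes the published 9-term model,
including its high-risk SV interval (1675, 2175), as shipped metadata — the
interval is a property of the original fitted surface and is not
recomputed. Risk indices band as: ≤ 1.5 no risk, ≤ 2 low, > 2 high
(boundaries belong to the lower band). `riskSurface()` estimates an
age-by-SV case-frequency surface by Nadaraya–Watson smoothing with a
Gaussian product kernel on a grid (default 46 age bins over 45–90 years by
50 SV bins); empty regions borrow from neighbours through the kernel. No
parametric surface fit is attempted because none is specified in the
source; the mapping from smoothed case frequency to the banded risk-index
scale is the documented convention $\mathrm{index} = 1 + 2 \cdot
\mathrm{frequency}$, under which the thresholds 1.5 and 2 correspond to
case frequencies of 25% and 50%. The original "33 ranks of risk index" is
not implementable from the published description; only the three bands and
the continuous index are exposed.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `penaltyGrid` | 1, 2, ..., 256 (powers of 2) | — | exact value set observed in the published per-prefix tuning |
| `bandwidthGrid` | 0.1, 0.2, 0.3, 0.5, 1, 2, 4, 8 | feature SD after fold standardisation | likewise |
| `cvFolds` | 10 | — | the study's protocol |
| selection threshold | 0.5 | share of total weight | "more than 50%", strict |
| infogain/chi2 bins | ≤ 10 equal-frequency | — | the source never states a discretization; quantile bins are robust to skewed laboratory values |
| Relief | full deterministic sweep, 1 nearest hit/miss, Manhattan distance | scaled features | reproducibility; the classic randomized variant sits behind `nIterations` + `seed` |
| surface bandwidths | axis range / 10 | years, SV units | grid-resolution-matched default; widen for variance control at small n (see below) |

Ties in grid tuning resolve toward smaller $C$, then smaller $q$. Features
are standardized inside each training fold only; fold assignment is
stratified (fold sizes within 1, per-fold class counts within 1 of
proportional) and fully determined by the seed.

Degenerate inputs: a constant feature min-max normalises to all zeros; a
Fisher score with zero within-class variance but separated means receives
ten times the largest finite score (ranks first, no infinities); a
single-feature curve has one prefix and contribution 1; an all-zero weight
vector is a hard error.

## The synthetic cohort generator

`generateSyntheticCohort()` emulates the *structure* of the reference
cohort: two near-balanced classes (default 398/792 cases), informative
features drawn class-conditionally Gaussian with means `effectSize` pooled
standard deviations apart, pure-noise features identically distributed in
both classes, affine placement on plausible clinical scales (base level
20–200 units, spread 10–30% of base), and roughly half the features
rounded to whole numbers like integer-valued laboratory items. Defaults
are 792 subjects, 9 informative + 19 noise features, effect size 1.

What it does *not* emulate: inter-feature correlation (real blood panels
are strongly correlated), non-Gaussian marginals, label noise, and
age-structured risk. Passing tests on this generator therefore demonstrate
algorithmic correctness and sane statistical behaviour, not clinical
performance on real cohorts — the original cohort is not publicly
deposited, so its headline classification figures can only be checked
where they follow arithmetically from published counts.

Simulation-scale runs in the tests and examples use a reduced wrapper
configuration — 3-fold cross-validation with $C \in \{1, 16\}$, $q = 2$ —
and cohorts of 40–800 subjects with 4–20 features; the full grids remain
the package defaults. The recovery study uses 20 replicate seeds at
n = 800 with 5 informative of 20 features.

## Design choices where the source is open

* **Selection parsimony vs full recovery.** The strict >50% rule is
  deliberately parsimonious. When a few planted features concentrate the
  fused weight, the minimal prefix crosses 50% before exhausting them:
  with five equally weighted strong features the prefix stops at three.
  Full recovery of a planted set is thus *not* implied by the selection
  rule even when the weighting ranks every planted feature on top; the
  weighting order and the selected panel should be read together.
* **Tournament coefficient bookkeeping.** Coefficients are recorded at
  full precision and a model keeps its maximum across rounds; integer
  rounding happens only in reports.
* **First-ranked contribution.** Assigned 1.00 rather than left undefined,
  following the published per-filter table; this rewards each filter's top
  pick and is what makes the cumulative columns start at 1.
* **Label-blind spread scorer.** The standard-deviation filter never sees
  the labels; on weak effects (d ≤ 2) it cannot reliably place informative
  features above noise (the mixture inflates the scaled SD by only
  $\sqrt{1+d^2/4}$ against min-max range noise). This is inherent to the
  scorer, and one of the motivations for fusing several filters.
* **Surface smoothing.** The default bandwidth (a tenth of each axis
  range) matches the default grid resolution. For flatness checks or
  small cohorts, wider bandwidths (a fifth of the range) keep the
  cell-level standard error small; the surface is an exploratory display,
  not an inferential estimate.
* **Baseline optimal prefix.** In method comparisons each single-filter
  baseline picks the prefix length with peak cross-validated accuracy on
  the same folds used for reporting — optimistically biased, but it is
  the protocol of the original comparison and is applied evenly.

## Known limitations

* The effectiveness coefficients and fused weights inherit the scale of
  $W$ and $D$; they are comparable within a run, not across cohorts.
* Pooled (micro) confusion counts across folds are reported, so accuracy
  is exactly (TP+TN)/n; per-fold metric averaging would differ slightly.
* No nested cross-validation: tuned accuracies are model-selection
  optimistic.
* The Relief variant is the classic single-neighbour form on Manhattan
  distance, not ReliefF with k neighbours.
* Information gain and the chi-squared statistic depend on the
  discretization; with ≤ 10 equal-frequency bins the chi-squared null mean
  is about the table's degrees of freedom, so raw chi-squared scores are
  not near zero under independence (their *ranking* is what the pipeline
  uses).
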