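---
title: "Methods: harmonization, ranking and nested-CV evaluation of MRI volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonization, ranking and nested-CV evaluation of MRI volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mciharmonix)
```

This vignette is the package's own account of the statistical machinery:
what is modelled, which knobs matter, what the synthetic generator does and
does not emulate, and where genuinely open design choices were settled.

## The problem

Baseline regional brain volumes of elders who later convert to mild
cognitive impairment (uHC) differ subtly from those who stay healthy (HC).
Three obstacles dominate any analysis of such tables: nuisance covariates
(age, sex, head size) carry far more variance than the disease signal;
cohorts are heavily imbalanced (roughly four stable elders per converter);
and aggressive model tuning on small samples produces optimistic
performance estimates. The package addresses the three in order:
reference-group harmonization, cost-compensated or rebalanced
classification, and nested cross-validation.

## Harmonization model

For each volume feature and each sex stratum, an ordinary-least-squares
polynomial surface on (age, ICV) is fitted using only HC rows. The default
degree is `poly11` (a plane: intercept, age, ICV). A `poly22` option adds
age², age·ICV and ICV²; it exists for demonstrating curvature, but with a
few hundred reference subjects per sex the quadratic fit is noticeably
biased at the covariate borders, so the linear surface is the default.

Residual harmonization subtracts the predicted mean; z-score harmonization
also divides by the prediction SD. Two choices deserve justification:

* **Observation-level SD.** `sigma_hat = sqrt(mse * (1 + h))`, where `h` is
  the leverage of the query point. The `1 +` term makes `sigma_hat` the SD
  of a new observation rather than of the fitted mean; this matches the
  prediction-interval convention of the curve-fitting routine the procedure
  emulates and keeps z-scores approximately unit-variance on reference
  data. A `level = "mean"` flag exposes the other convention.
* **Never refit on non-reference rows.** uHC rows are scored with the
  HC-fitted model of their sex. Refitting on patients would absorb disease
  signal into the nuisance model.

Queries outside the reference covariate hull are computed but flagged,
since leverage (and hence z-score shrinkage) grows at the borders where
reference points are scarce.

## Synthetic cohort generator

Each region follows

```
volume = intercept_sex + age_slope * age + icv_coef * ICV
         + uhc_effect * 1{converter} + N(0, noise_sd),  floored at 1 mm^3
```

with ages uniform over 60–86 (a truncated-normal mode exists for matching
published cohort means), converter ages shifted +3 years (the age
confound harmonization must absorb), and ICV Gaussian per sex (males
1.55M mm³, females 1.38M mm³, SD 0.13M). Sex affects volumes only through
ICV and the intercepts are shared, so harmonized sex differences should
vanish — a property the tests assert.

Calibration targets, chosen once: each region's HC marginal mean and SD
match the reference cohort's printed values, and the eight effect regions
(two ventricular measures, hippocampus, accumbens, entorhinal, lateral
orbitofrontal, middle temporal, whole-brain-minus-ventricles) carry the
printed converter-minus-stable mean differences. The split of marginal
variance between ICV, age and residual noise is the one the reference
cohort's *harmonized* test results imply: back-computing effect sizes from
the printed per-test p-values at n = (97, 24) pins down each effect
region's post-harmonization residual SD (`d = t * sqrt(1/97 + 1/24)`,
`resid = |effect| / d`), capped where the implied residual exceeds what
the marginal SD allows (both ventricles, accumbens), with the ICV
correlation kept at least 0.2. Non-effect cortical regions use a generic
split (ICV r = 0.65, age 10% of variance); the global brain measure is
almost entirely ICV-driven (r ≈ 0.96). Ventricles get positive age slopes
(they enlarge with age), all other regions negative.

What the generator does **not** emulate: cross-region correlation of the
noise (no covariance structure is published for it), longitudinal change,
site or scanner effects, and non-Gaussian tails. Passing tests therefore
demonstrate that the pipeline's machinery is correct and well calibrated
under its stated assumptions — not that real conversion is this separable.
Indeed with independent noise across eight informative regions the
synthetic classification problem is easier than the real one, and the
classifier metrics on synthetic cohorts run well above published values on
real data; only directional conclusions (balanced > imbalanced, positive
optimism gap, harmonization helping the tests) transfer.

## Feature ranking and subsets

Scores per feature: one-way ANOVA, Kruskal–Wallis and chi-square as
`-log(p)` (natural log; a base-10 flag exists), ReliefF weights, and an
ANCOVA p-value for the group term on *uncorrected* values with age, sex,
education and ICV covariates (partial F, sex as a binary indicator).
Numerical conventions:

* chi-square discretizes into 10 equal-frequency bins on the pooled
  sample; features with at most 10 distinct values are used as categories
  directly; bins empty in both groups are dropped with the degrees of
  freedom adjusting automatically.
* ReliefF uses every observation as an anchor, k = 10 hits/misses,
  Manhattan distance on range-scaled features; a constant feature has
  zero range, its diff is defined as 0, and its weight is exactly 0.
* Percentages are `100 * score / sum(positive scores)`; non-positive
  scores (possible only for ReliefF) map to percentage 0 but still count
  in the four-way average's denominator.

Subsets: (A) mean-of-four-percentages at or above the median — "at or
above", so ties are included; (B) ReliefF weight strictly positive;
(C) the intersection of all six criteria columns (per-method medians,
ReliefF positivity, the average rule, the significance rule); (D) the
significance rule alone — Bonferroni-adjusted (over the 40 features)
p ≤ 0.05 simultaneously in ANOVA and Kruskal–Wallis on harmonized values
and ANCOVA on uncorrected values. Running the location tests on harmonized
values is deliberate: an uncorrected two-group test can miss a real effect
that covariate variance swamps (the hippocampus is the canonical example),
which is precisely the argument for harmonizing before selection.

## Classifiers

Five families behind one fit/predict contract, with the tuning spaces:
naive Bayes (normal vs kernel densities; box / epanechnikov / normal /
triangle smoothers; bandwidth); KNN (neighbors 5–30, eleven distance
functions); SVM (gaussian = rbf, linear, polynomial; kernel scale and box
constraint in [0.1, 10], both log-scaled); lasso-logistic (λ in
[10⁻³, 10]); RUSBoost (cycles, shrinkage in (0, 1], maximal splits). Plus
a constant-prediction majority baseline used for degenerate-behaviour
checks.

Decisions worth recording:

* The kernel-NB bandwidth is parameterized as a multiplier of each
  feature's robust SD, boxed to [10⁻², 10²] (default: Silverman's factor
  0.9·n^(−1/5)). An unbounded positive space cannot be searched by a
  surrogate model; the box covers everything from near-interpolation to
  near-uniform smoothing.
* RUSBoost cycles and maximal splits are likewise boxed (10–200, 1–128,
  log-scaled) for the same reason.
* Gaussian-NB variances are floored at 10⁻⁹ of the feature variance.
* The logistic score transformation ("none"/"logit"/"invlogit"/
  "doublelogit") is monotone, so it cannot change predicted labels; it is
  applied to reported scores only.
* KNN's hamming and jaccard distances are defined on features binarized at
  the per-feature training median, since they are otherwise undefined on
  continuous volumes.
* Cost sensitivity is realized as class weights (w_uHC = δ, w_HC = 1).
  For risk-minimizing classifiers this is exactly the cost matrix
  `[[0,1],[δ,0]]`; for naive Bayes the equivalence is analytic (the
  posterior-odds threshold shifts by δ) and is tested as such. RUSBoost
  never receives δ — its internal undersampling already rebalances.

## Nested cross-validation and optimization

Outer stratified K-fold (default 10; per-class counts differ by at most
one per fold). On each training part an inner (K−1)-fold CV defines the
tuning objective — cost-weighted misclassification, consistent with δ
entering training — which a Gaussian-process optimizer minimizes:
initial random design of max(10, budget/5) points, squared-exponential
kernel on unit-scaled (log-transformed where marked) coordinates with
one-hot categoricals, lengthscale and noise chosen by marginal likelihood
on small grids, expected improvement over 256 random candidates per step.
A pure-random-search fallback sits behind the same contract. The winner is
refit on the full training part and predicts the holdout; holdout
predictions pool into one confusion table per replication (per-fold
averaging is available by flag; pooling is primary because single folds of
a 121-subject cohort contain only 2–3 converters). The inner-CV confusion
of the selected configuration is also recorded — the *direct* estimate,
whose excess over the nested estimate measures tuning optimism.

Monte Carlo replication re-randomizes partitions (and, in balanced mode,
the undersample) with seeds derived deterministically from a master seed;
identical configurations reproduce bit-identical results tables. Failed
folds are counted and reported rather than silently dropped.

Replication metrics feed an N-way ANOVA over classifier / harmonization /
subset factors, Tukey HSD pairwise comparisons (Tukey–Kramer for unequal
counts), and Benjamini–Hochberg FDR annotation, with subsets pooled for
the headline classifier ranking. Replications share underlying data, so
these p-values are approximate — the report says so rather than modelling
the dependence.

## Problem sizes

The shipped test configuration and the analysis scripts use desk-scale
settings chosen as the smallest sizes at which every qualitative property
is stable: k_outer = 5, 5 Monte Carlo replications, 30 optimizer
iterations, cohorts of 97/24 and 413/106, 50 replicates for effect-region
recovery, 100 for harmonization calibration, 20 for the optimism sign
test. The full-scale settings (K = 10, 20 replications, 200 iterations,
all five classifier families, all four subsets) run through exactly the
same entry points via `evaluation_config()`.

## Known limitations

* Independent noise across regions understates the multivariate difficulty
  of real data; absolute classifier metrics on synthetic cohorts are
  optimistic.
* The GP optimizer treats integer parameters by rounding a continuous
  relaxation; for spaces that are almost entirely categorical it degrades
  gracefully toward random search.
* ANCOVA and the harmonization share covariates, so subset D's three tests
  are strongly dependent; Bonferroni over features (not over the three
  tests) is the operative correction, as in the procedure it reimplements.
* No site/batch harmonization (single-site assumption) and no missing-data
  handling beyond rejection with an optional logged row-drop.
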