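---
title: "Methods: PBSI analysis of morphometric heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBSI analysis of morphometric heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A subject's regional morphometry is summarised as ordered profiles: 100
cortical parcel values for each of thickness (mm), surface area (mm²) and
grey-matter volume (mm³), plus 14 subcortical volumes (mm³). The
Person-Based Similarity Index for subject $s$ in diagnostic group $g$ and
measure class $m$ is the mean Spearman correlation between $s$'s profile and
the profiles of the other $n_g - 1$ group members. Spearman (not Pearson)
correlation makes the score invariant to any monotone rescaling of a
subject's profile, so it captures the *shape* of the regional pattern, not
its overall level.

Raw scores live in $[-1, 1]$ and are typically high (a shared anatomical
template dominates); the informative signal is their spread. Raw scores are
z-scored against the analysed sample and aggregated: the Cortical composite
averages the three cortical z-scores, the Total composite all four, each
re-standardized so every reported column has reference mean 0 and SD 1.

Two conventions were genuinely open and are set as defaults with a switch:

* **z-scoring reference** (`zscore_ref`): pooled across all groups
  (default) or within group. Pooling keeps the groups on a common scale —
  within-group standardization would erase exactly the group differences the
  analysis is about.
* **composite construction**: composites average *z-scored* components
  (then re-standardize). Averaging raw correlations would let the class with
  the widest raw spread dominate; averaging z-scores is scale-free and is
  the convention in the PBSI literature.

Minimum group size is 3 (at least two correlations per mean); smaller groups
error rather than return degenerate scores. Ties are handled with average
(fractional) ranks and a tie-aware Pearson-on-ranks formula, so integer
valued inputs are exact. Constant profiles are rejected: their rank
correlation is undefined.

## The synthetic cohort

No subject-level data accompany the study design this package addresses, so
the generator *is* the test bed. For subject $s$ at site $b$ in group $g$,
region $r$, class $m$:

$$y = (\mu_{m,r} + \sigma_g\,\tau_{m,r}\,d_{s,r})\cdot
      \mathrm{scale}_{b,m,r} + \mathrm{shift}_{b,m,r} + \varepsilon$$

with $d_{s,r} \sim N(0,1)$ i.i.d. across regions, measurement noise
$\varepsilon \sim N(0, (\text{noise\_sd}\cdot\mu_{m,r})^2)$ (noise is
expressed as a fraction of the region mean so one scalar spans mm and mm³),
and values clipped at 1% of $\mu_{m,r}$ — thickness and volumes are
physically positive, and a floor that deep leaves rank statistics intact.
The dispersion multiplier $\sigma_g$ is the heterogeneity knob: it scales
how far each subject deviates from the shared regional template, so larger
$\sigma_g$ lowers every pairwise correlation and with it the expected PBSI.

Defaults state a world a morphometry researcher would recognise:

* region means: thickness $\approx 2.5 \pm 0.25$ mm across parcels, area
  and volume log-normal around 450 mm² and 1300 mm³, subcortical volumes at
  canonical values (thalamus ≈ 7000 mm³ … accumbens ≈ 600 mm³ with slight
  L/R asymmetry). They are fixed package constants (own RNG stream), not
  functions of the user's seed.
* between-subject scales: coefficients of variation 5% (thickness), 10%
  (area), 12% (volume), 8% (subcortical).
* measurement noise 2% of the region mean.
* the `"paper-like"` preset: 59 controls / 41 recent-onset / 32 chronic,
  sites assigned as in the source cohorts (20/39/0, 34/7/0, 0/11/21),
  multiplicative site scales 0.97/1.00/1.05 and additive shifts −1%/0/+2%
  of the region mean, dispersion 1 / 1.6 / 2.0. Site-effect magnitudes are a
  free parameter (scanner details are not published); these values produce
  site η² of a few percent, typical of multi-scanner morphometry.
* clinical scores: distributions follow the published demographics (PANSS
  total 62.6 ± 16.2 vs 68.3 ± 18.7, GAF 44.8 ± 14.5 vs 62.1 ± 11.0, FSIQ
  119.9/100.7/83.0, durations on the two sides of the 5-year split, doses
  16.9 vs 20.5 mg olanzapine-equivalent). One cohort site (AMC2) records no
  IQ/MQ/dose, exercising pairwise-complete correlation handling.

**Clinical coupling.** PANSS totals are baseline
$+\,k\,(\mathrm{RMS}(d_s) - 1)\,+$ noise, where $d_s$ is the subject's
deviation vector for the surface-area class — deviant brains score sicker.
Subscales split the total with PANSS item-count weights (7/7/16) and sum to
it exactly. $k = 200$ was calibrated once, by pilot simulation at
$n = 1000$ before any acceptance test existed, so the population
correlation between surface-area PBSI and PANSS total is about $-0.5$ in
the recent-onset group — the magnitude the study design reports. It was not
revisited afterwards.

What the generator does **not** emulate: spatial correlation between
regions is off by default (`factor_weight = 0`; a shared low-rank factor is
available because real morphometry is spatially correlated, but the
independent null is analytically clean), there are no sex or age effects on
morphometry (keeping the matching tests interpretable), no longitudinal
structure, and no non-Gaussian tails. A green test therefore establishes
correctness of the *pipeline mechanics and statistics under the stated
model*, not robustness to everything real MRI data does.

## Harmonisation

ComBat is implemented in the parametric empirical-Bayes form: per-feature
standardization by the grand mean plus protected covariate effects
(diagnostic group, treatment-coded with controls as reference) and the
pooled residual SD; per-batch location/scale estimates shrunk toward
batch-level priors (normal for location, inverse-gamma for scale, moment
matched hyperparameters); iterative conditional updates until the relative
change is below 1e-4 or 100 iterations. Each measure class is harmonised in
a separate fit — the classes live on different scales and pooling them
would distort the EB priors. A single batch yields the identity adjustment
with a warning; a batch of one subject is an error; unseen batch labels at
apply time are an error (no out-of-sample batch imputation). The
implementation is validated against the exact non-EB location/scale
adjustment, to which EB converges as batch sizes grow; at $n = 100$ per
batch the EB estimate still carries per-feature noise of order
$n^{-1/2}$, so the shift-removal check is stated on the mean absolute
per-feature batch gap rather than the maximum.

## Group statistics

* **Matching**: greedy nearest-neighbour on age within exact sex strata,
  1 : ratio without replacement, distance ties broken by a seeded shuffle.
  On preset cohorts the pipeline default is matching *off*: the presets
  emulate the already-matched sample (59/41/32), and re-matching would
  shrink it. The stage is available (`match = list(enable = TRUE)`) and
  tested.
* **Outliers**: per group and per PBSI measure, values outside
  $[Q_1 - 1.5\,\mathrm{IQR},\, Q_3 + 1.5\,\mathrm{IQR}]$ with type-7
  (linear-interpolation) quartiles are set missing. Default policy is
  per-measure (a subject flagged on area still contributes to thickness);
  listwise is available. Exclusion happens on raw scores, before
  z-scoring, so one outlier cannot drag the standardization scale.
* **Comparison**: per score, OLS on group + age + sex (controls reference);
  a one-way ANOVA on the same filtered scores without covariates as a
  companion; Tukey–Kramer pairwise tests using the studentized range with
  unequal-$n$ standard errors. At $k = 2$ the Tukey p equals the pooled
  t-test p (numerically to ~1e-8, the accuracy of the studentized-range
  CDF).
* **Clinical correlations**: Pearson with the t transform, pairwise
  complete, seven variables per (PBSI measure × patient group) forming one
  Benjamini–Hochberg family ("seven comparisons"). Illness duration and
  antipsychotic dose are summarised descriptively but are not part of the
  seven-test family. BH (not BY) is used; the step-up values are clamped to
  be no smaller than the raw p, guarding a 1-ulp rounding artefact of
  `p * m / rank`.

## A known statistical limitation, kept red

One acceptance property asks that ANOVA p-values on null-cohort PBSI scores
be uniform. They are not, and cannot be made so by any generator setting:
PBSI scores within a group are mutually dependent, because every score is a
mean over pairwise correlations shared with the other members. The group
mean PBSI is a degree-2 U-statistic whose sampling variance is roughly
$4\sigma_1^2/n$, while the ANOVA denominator, built from the within-group
spread of individual scores, expects $\sigma_1^2/n$ under independence.
Empirically, null cohorts reject at the 0.05 level in ~47% of runs
(KS $D \approx 0.46$). The machinery itself is calibrated: feeding the same
ANOVA/Tukey code *independent* scores drawn from one distribution gives
uniform p-values (KS p ≈ 0.06 over 2000 replicates). The inflation is a
property of the PBSI construction — and applies equally to significance
tests in the applied literature that treats PBSI scores as independent
observations. The corresponding check is left failing by design, with this
analysis as its documentation; group-difference p-values on PBSI scores
should be read as descriptive unless the dependence is modelled (e.g. by
permutation of group labels with re-computation of scores).

## Numerical choices

* Spearman is computed as Pearson on average ranks via centred
  cross-products; the pairwise function and the matrix path used for whole
  cohorts are cross-checked to 1e-13.
* EB convergence tolerance 1e-4 (relative), max 100 iterations.
* Correlations are clamped to $[-1, 1]$ against floating-point overshoot.
* All cohort randomness flows from one integer seed; derived child seeds
  stay below $2^{31}$. Fixed seed ⇒ byte-identical written outputs (the
  manifest records config hash, seed and per-file checksums, and excludes
  the output path so bundles compare across directories).
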