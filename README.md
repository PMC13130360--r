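# pbsi — Person-Based Similarity Index analysis of regional brain morphometry

Case–control neuroimaging studies compare group means, but in disorders such
as schizophrenia the more striking phenomenon is *inter-individual
heterogeneity*: patients differ from each other more than controls do. The
Person-Based Similarity Index (PBSI) quantifies this per subject. Given a
regional morphometric profile **x**ₛ (e.g. cortical thickness over 100
parcels, in canonical atlas order), the subject's score within their
diagnostic group of size *n* is

```
PBSI(s) = (1 / (n−1)) Σ_{t ≠ s} ρ(x_s, x_t)
```

where ρ is Spearman's rank correlation. Lower PBSI = a profile less like the
subject's peers = greater heterogeneity. Scores are computed separately for
cortical thickness, surface area, grey-matter volume (100 parcels each) and
14 subcortical volumes, z-scored against the analysed sample, and aggregated
into **Cortical** (thickness + area + volume) and **Total** (all four)
composites.

The package implements the full analysis pipeline for three-group designs
(healthy controls, recent-onset schizophrenia ≤ 5 years, chronic > 5 years):

* **synthetic cohorts** — a generator with per-group dispersion multipliers,
  three-site additive/multiplicative batch effects, and optional coupling of
  a subject's structural deviation to PANSS symptom severity;
* **ComBat harmonisation** — parametric empirical-Bayes location/scale batch
  adjustment, protecting diagnostic group as the sole covariate;
* **group analysis** — age/sex greedy nearest-neighbour matching,
  1.5 × IQR outlier exclusion, OLS adjusted for age and sex, one-way ANOVA
  with Tukey–Kramer post-hoc tests;
* **clinical associations** — Pearson correlations of PBSI scores with seven
  clinical variables (PANSS positive/negative/general/total, IQ, MQ, GAF),
  Benjamini–Hochberg FDR within each seven-test family;
* **pipeline** — one reproducible run with logging and a hashed manifest.

## Worked example

```r
library(pbsi)
res <- run_pipeline(run_config("paper-like", seed = 17))
aggregate(z_total ~ group, data = res$scores, FUN = mean)
```

The `"paper-like"` preset simulates 59 controls / 41 recent-onset / 32
chronic patients over three sites with dispersion multipliers 1 / 1.6 / 2.0.
Group means of the six PBSI columns (seed 17):

```
    group z_thickness z_area z_volume z_subcortical z_cortical z_total
  chronic       -0.89  -0.92    -0.92         -0.36      -0.91   -0.85
       HC        1.04   1.02     1.03          0.58       1.06    1.03
   recent       -0.79  -0.71    -0.76         -0.61      -0.75   -0.79
```

Both patient groups sit well below controls on every PBSI measure — the
heterogeneity signature. Tukey–Kramer contrasts on `z_total`:

```
  group1 group2  diff    p_adj
 chronic     HC  1.88 1.31e-14
 chronic recent  0.06 8.02e-01
      HC recent -1.82 1.31e-14
```

and the surface-area PBSI correlates negatively with PANSS severity in the
recent-onset group (FDR-adjusted within the seven-variable family):

```
 clinical_variable  n      r p_fdr
    PANSS positive 41 -0.387 0.022
    PANSS negative 41 -0.436 0.010
     PANSS general 41 -0.486 0.008
       PANSS total 41 -0.463 0.008
                IQ 34  0.191 0.390
                MQ 34  0.057 0.840
               GAF 41 -0.032 0.840
```

Subjects simulated with larger structural deviation get both lower
surface-area PBSI and higher PANSS scores, so the correlation is negative by
construction; its magnitude reflects the generator's calibrated coupling.

## Command line

```sh
Rscript inst/cli/pbsi.R simulate --preset paper-like --seed 17 --out cohort/
Rscript inst/cli/pbsi.R run --in cohort/ --out report/
```
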