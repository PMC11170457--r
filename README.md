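# actijive

Integrative modeling of accelerometry-derived sleep (SL), physical
activity (PA) and circadian rhythm (CR) domains, and their association
with depression phenotypes.

Minute-epoch wrist-accelerometer counts carry three intertwined views of
the 24-hour sleep-wake cycle. Features computed from them — sleep timing
and continuity, activity volume and fragmentation, rest-activity rhythm
strength and phase — are strongly correlated within and across domains
because they all derive from one signal, which makes side-by-side
regression on dozens of features unstable. `actijive` addresses this with
a **Joint and Individual Variation Explained (JIVE)** decomposition: the
three feature blocks are split into a low-rank joint part shared across
domains, low-rank block-specific individual parts and residual,

    X_k = J_k + A_k + E_k,   J_k = U D V_k',   A_k = U_k D_k W_k',   U' U_k = 0

(subjects in rows, k ∈ {SL, PA, CR}). The orthogonal subject scores then
enter a logistic regression of a depression contrast (lifetime / current /
remitted vs none) simultaneously, adjusted for covariates, with odds
ratios per 1 SD of score.

The package is aimed at biostatisticians and psychiatric-epidemiology
groups working with actigraphy cohorts. The reference cohort is not
publicly deposited, so the package ships a two-tier synthetic generator —
feature-level blocks with planted factor structure and outcome model, and
minute-level epoch streams with planted sleep windows, two-state activity
bouts and a cosinor envelope — giving every pipeline stage a ground truth
to validate against.

## What is implemented

- `read_epochs()` / `segment_days()` / `apply_inclusion()` — epoch CSV
  ingestion, noon-to-noon day grid, the strict >16 h wear validity rule and
  the ≥7-valid-day inclusion filter.
- `detect_sleep_period()` / `sleep_summary()` — count-based sleep-period
  detection (or GGIR-style annotation ingestion) and the 7 sleep features
  (Onset, Wakeup, Duration, Midpoint, Efficiency, NWB, NSB).
- `pa_volume()` / `pa_composition()` / `pa_fragmentation()` — TAC, TLAC,
  TST, LiPA, MVPA and the transition probabilities SATP, ASTP.
- `cosinor_fit()` / `iv_is()` / `l5_m10()` / `diurnal_fpca()` — Mesor,
  Amp, Acro (negative-radian convention), IV, IS, RA, L5/M10 with times,
  and fPC1-4 of the diurnal profile; `extract_features()` assembles the
  full 7 + 7 + 14 battery.
- `preprocess_blocks()` / `select_ranks()` / `fit_jive()` /
  `extract_scores()` — the JIVE core with permutation rank selection and
  the per-block joint/individual/residual variance partition.
- `descriptive_table()` / `jive_logistic()` — group comparisons
  (chi-square / ANOVA) and the per-contrast score regressions.
- `feature_plan()` / `generate_feature_cohort()`, `epoch_plan()` /
  `generate_epoch_cohort()` — the synthetic cohorts; `run_pipeline()` — a
  config-driven runner with a deterministic manifest.

The numbered scripts under `analysis/` run the whole study on synthetic
data (simulate → features → JIVE → associations → report), writing tables
to `results/`.

## Worked example

```r
library(actijive)

plan   <- feature_plan(n = 600)                     # defaults emulate the study conditions
cohort <- generate_feature_cohort(plan, seed = 1)
fit    <- fit_jive(preprocess_blocks(cohort$blocks), 3L, c(SL = 1L, PA = 2L, CR = 3L))
fit
#> <jive_model> n = 600; ranks: joint 3, SL 1, PA 2, CR 3; converged after 43 iterations
#> variance explained (fractions):
#>    joint individual residual
#> SL 0.556      0.359    0.085
#> PA 0.710      0.258    0.031
#> CR 0.561      0.293    0.147

jive_logistic(extract_scores(fit), cohort$covariates, contrast = "lifetime")
#> Contrast: lifetime (288 cases vs 312 controls)
#>  predictor               or     p_value
#>    Joint_1 0.78 (0.66-0.93) 0.004578830
#>    Joint_2 1.08 (0.91-1.28) 0.391110528
#>    Joint_3 1.01 (0.86-1.20) 0.862711644
#>       SL_1 0.81 (0.68-0.96) 0.013568641
#>       PA_1 1.02 (0.86-1.21) 0.784504917
#>       PA_2 1.25 (1.06-1.49) 0.009883494
#>       CR_1 1.06 (0.90-1.26) 0.486215794
#>       CR_2 1.15 (0.97-1.36) 0.113000601
#>       CR_3 1.07 (0.90-1.27) 0.435482412
```

Reading this: roughly 56%/71%/56% of the SL/PA/CR block variance is joint
across domains — cross-domain overlap dominates any single domain. The
odds ratios are per 1 SD of each orthogonal score; here the planted
protective effect on the first joint component (higher, less fragmented
activity) is recovered at 0.78 (component orientation follows a loading
sign convention, so individual runs may report a planted effect on the
reciprocal scale). At n = 600 the confidence intervals are wide; the
default plan's n = 2317 narrows them to the reported precision.

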