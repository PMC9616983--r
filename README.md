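# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
for bidirectional screens of many exposures (e.g. circulating inflammatory
markers) against continuous outcomes such as cognitive performance and
MRI-derived brain measures.

MR uses genetic variants as instrumental variables: because alleles are
randomly assorted at conception, a SNP that raises an exposure can stand in
for a randomized "dose" of it, sidestepping the confounding and reverse
causation that afflict observational associations. In the two-sample
design, the SNP–exposure effects (β̂ₓⱼ, SEₓⱼ) and SNP–outcome effects
(β̂ᵧⱼ, SEᵧⱼ) come from different GWAS cohorts, so only published summary
statistics are needed.

## What the package computes

For each SNP j the Wald ratio is β̂ⱼ = β̂ᵧⱼ / β̂ₓⱼ. The estimators pool
these ratios:

- **IVW** — inverse-variance-weighted meta-analysis with first-order
  weights wⱼ = β̂ₓⱼ² / SEᵧⱼ²; fixed-effect SE 1/√Σwⱼ, with multiplicative
  random-effects inflation √max(1, Q/(J−1)) when four or more SNPs are used.
- **MR-Egger** — weighted regression of β̂ᵧ on β̂ₓ with a free intercept;
  the intercept estimates average directional pleiotropy (valid under
  InSIDE), the slope is the pleiotropy-adjusted effect.
- **Weighted median** — the weighted 50th-percentile ratio; consistent when
  at least half the instrument weight is valid, with a parametric-bootstrap
  SE.
- **MR-PRESSO-style outlier procedure** — simulation-based global residual
  test, per-SNP outlier detection (Bonferroni), and a distortion test for
  the outlier-corrected estimate; reports itself unavailable below 4 SNPs.
- **Diagnostics** — Cochran's Q heterogeneity (Q = Σwⱼ(β̂ⱼ − β̂_IVW)², χ²
  on J−1 df), single-SNP and leave-one-out analyses.

Around the estimators: instrument selection at p ≤ 5e-8 with fallback to
5e-6 when fewer than 3 SNPs survive, cross-trait SNP exclusion, greedy LD
pruning (r² > 0.001 removes the larger-p SNP), per-SNP F = (β̂/SE)² and
R² = β̂²·2·MAF(1−MAF); allele harmonization with strand inference and
palindromic-SNP removal; reconstruction β̂ = z·SE with
SE = 1/√(2·MAF(1−MAF)(N+z²)) for z-only GWAS; analytic power for
continuous outcomes, β_min = (z₁₋α/₂ + z_pow)/√(N·R²); and grouped
Benjamini–Hochberg FDR across an analysis grid. A synthetic GWAS-pair
generator with known causal effect, controllable pleiotropy, LD blocks and
strand noise supports end-to-end validation.

## Worked example

Three pre-aligned SNPs with exposure effects (0.1, 0.2, 0.15), exposure SEs
(0.01, 0.02, 0.015), outcome effects (0.02, 0.05, 0.03), outcome SEs
(0.01, 0.02, 0.015) — Wald ratios (0.2, 0.25, 0.2) with equal weights 100:

```r
library(mrpipe)
we <- make_worked_example()
h <- harmonize_set(we$exposure, we$outcome)
mr_ivw(h)
#> ivw: beta = 0.2167 (95% CI 0.1035, 0.3298), se = 0.05774, p = 0.000175, nSNP = 3
#>   Q: 0.1667
#>   Q_df: 2
#>   Q_p: 0.92
#>   model: fixed
mr_weighted_median(h, seed = 7)
#> weighted_median: beta = 0.2 (95% CI 0.07146, 0.3285), se = 0.06558, p = 0.00229, nSNP = 3
```

The IVW estimate is the weighted mean of the ratios, 13/60 ≈ 0.2167 outcome
units per SD of exposure, with fixed-effect SE 1/√300 ≈ 0.0577; Q = 1/6 on
2 df (p = 0.92) shows no between-SNP heterogeneity, and the weighted median
lands on the middle ratio 0.2 — all three estimators agree, as they should
when no SNP is pleiotropic.

Power planning for an outcome GWAS of N = 33,536 with instruments
explaining 2% of the exposure variance:

```r
detectable_effect(n = 33536, r2 = 0.02)   # alpha 0.05, power 0.8
#> 0.1081766
mr_power(n = 33536, r2 = 0.02, beta = 0.103)
#> 0.7603898
```

Whole grids run from a config — `run_forward(cfg)` selects instruments per
exposure (with the 5e-6 fallback), harmonizes, runs every estimator and
diagnostic per exposure×outcome cell, and applies grouped FDR;
`run_reverse(cfg)` swaps roles at the genome-wide threshold only, first
removing SNPs shared by the two cortical traits. See
`vignette` source `vignettes/mr-methods.Rmd` for the full model
description and `?run_config` for the options.

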