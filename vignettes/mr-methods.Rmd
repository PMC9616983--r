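---
title: "Methods: two-sample MR estimation, diagnostics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation, diagnostics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# The model

Two-sample Mendelian randomization treats each SNP j as an instrument for
an exposure X. The structural model underlying every routine in this
package is

* SNP–exposure effect: gamma_j (SD of exposure per effect allele),
* direct (pleiotropic) SNP–outcome effect: alpha_j,
* causal effect of interest: beta (outcome units per SD of exposure),
* true SNP–outcome effect: Gamma_j = beta * gamma_j + alpha_j.

The observed summary statistics are noisy versions of gamma_j and Gamma_j
with standard errors determined by allele frequency and GWAS sample size.
A valid instrument has alpha_j = 0; the estimators differ in how much
pleiotropy they tolerate:

* **IVW** assumes alpha_j = 0 for all SNPs. It is the inverse-variance
  weighted mean of the per-SNP Wald ratios r_j = by_j / bx_j with
  first-order weights w_j = bx_j^2 / se_y_j^2.
* **MR-Egger** allows directional pleiotropy provided instrument strength
  is independent of the direct effects (InSIDE). Each pair is oriented so
  bx_j > 0, then by is regressed on bx with a free intercept and weights
  1 / se_y_j^2; the intercept estimates the average direct effect and the
  slope is the adjusted causal estimate.
* **Weighted median** is consistent whenever valid instruments carry more
  than half the total weight.
* The **PRESSO-style procedure** assumes >50% valid instruments, balanced
  pleiotropy and InSIDE, and removes individual outliers.

# Estimation details and numerical choices

**Weights.** First-order weights (outcome SE only) are used throughout,
matching the long-standing default of the standard MR tooling. The
uncertainty of bx enters through the parametric bootstrap (weighted
median) and the parametric simulations (PRESSO), which resample both
coordinates.

**IVW fixed vs random effects.** The fixed-effect SE is 1/sqrt(sum(w)).
With J >= 4 SNPs the default is the multiplicative random-effects model,
inflating the SE by sqrt(max(1, Q/(J-1))); below 4 SNPs the heterogeneity
estimate is too unstable and the fixed model is used. The result records
which model ran. The max(1, .) floor means the CI is never narrower than
the fixed-effect one. This inflation also absorbs the extra ratio
dispersion caused by noise in bx, which first-order weights ignore — with
strong instruments the effect is small, and the coverage simulations below
confirm nominal behaviour.

**Cochran's Q** is always computed about the fixed-effect IVW center
(the standard definition), and the same Q drives the random-effects
inflation — a single source of truth, asserted by test.

**MR-Egger inference** uses a multiplicative residual scale bounded below
by 1 (no deflation when the fit is better than chance) and a t reference
with J - 2 degrees of freedom for both the slope and intercept. All bx
are made positive by flipping (bx, by) pairs jointly; this leaves every
Wald ratio unchanged and fixes the sign convention the intercept needs.
A design in which all |bx| are equal is rejected as degenerate.

**Weighted median.** Ratios are sorted, weights normalized, and the
estimate is the linear interpolation of the cumulative-weight midpoints
p_k = S_k - w_k/2 at 0.5. The SE is a parametric bootstrap (default 1000
resamples, explicit seed). An exhaustive grid search over the same
definition serves as the test oracle.

**PRESSO-style tests.** The global statistic is the weighted residual sum
of squares RSS = sum_j w_j (by_j - beta_(-j) bx_j)^2 with leave-one-out
IVW slopes. Its null distribution comes from parametric simulations of
(bx, by) around the fitted no-pleiotropy model; empirical p-values use
(1 + exceedances) / (1 + n_sim) so a p-value of zero is impossible. The
per-SNP outlier test compares each observed weighted squared residual to
its simulated distribution with Bonferroni correction at alpha/J. The
distortion test compares the shift between all-SNP and outlier-removed
IVW estimates against removal of random same-size subsets drawn from all
SNPs — a simplification of the original non-outlier bootstrap with the
same interpretation at these scales. Below 4 SNPs the procedure reports
itself "unavailable" rather than erroring, so pipeline cells degrade
gracefully; n_sim below 100 is refused as too coarse for an empirical
p-value.

**Wald-ratio edge cases.** bx = 0 is an error for a single ratio and a
logged skip in the single-SNP analysis. p-values are clamped away from
exact zero at the smallest positive double.

# Instrument selection

Selection per exposure runs: cross-trait exclusion, p-value thresholding,
greedy LD pruning, then QC. The primary threshold is 5e-8; when fewer
than 3 SNPs survive, selection falls back to 5e-6 (recorded in the
report). Pruning visits SNPs by ascending p (ties broken by chromosome,
position, then id, for determinism) and accepts a SNP iff its r-squared
with every accepted SNP is at most 0.001 — "LD > 0.001" is read as
r² > 0.001, the clumping convention; absent pairs count as zero.

Open choices resolved here: the threshold defining "associated with more
than one exposure" is taken to be the selection threshold itself (no
separate value is established for it); F-statistics are per-SNP Wald
forms (beta/se)^2 — consistent with per-instrument ranges being reported
in this literature — with the R²(n-2)/(1-R²) form available as an option
(the two agree asymptotically); allele frequencies are treated as
effect-allele frequencies with MAF = min(eaf, 1 - eaf). SNPs lacking a
frequency contribute no R² (warned) and cannot be palindrome-resolved.

For z-only GWAS the coefficient is reconstructed as beta = z * se with
se = 1/sqrt(2 MAF (1 - MAF) (N + z^2)); beta/se reproduces z exactly.

# Harmonization

Outcome records are aligned to the exposure's effect allele in rule
order: exact match (kept), swapped alleles (sign flip), strand complement
possibly with swap (corrected), palindromic A/T or C/G pairs, anything
else dropped as incompatible. Palindromes are resolvable only when both
allele frequencies exist and fall outside the ambiguity window, in which
case the minor-allele orientation decides the strand; otherwise they are
dropped. The window defaults to [0.42, 0.58] — the conservative community
default, configurable up to [0, 1] to drop all palindromes; the frequency
rule is an artifact choice since no published rule accompanies the
palindrome-removal step being emulated. Missing instruments are logged,
never proxied. Harmonization is an involution (re-harmonizing aligned
data is the identity) and the Wald ratio is invariant to allele
reorientation — both property-tested.

# Power and multiplicity

For a continuous outcome the detectable standardized effect at two-sided
level alpha and target power is (z_{1-alpha/2} + z_pow)/sqrt(N R²), and
conversely power = Phi(sqrt(N R²) |beta| - z_{1-alpha/2}) — the
normal-approximation (mRnd-style) formulae, using the dominant tail of
the two-sided test (the neglected tail is numerically irrelevant at any
realistic setting; at beta = 0 power is alpha/2 by construction). The
printed detectable effects this reproduces are standardized; outcome
units for MRI measures inherit whatever scale the outcome GWAS used.

FDR adjustment is Benjamini–Hochberg step-up applied independently within
configured groups. The default grid profile follows the emulated design:
each cognitive trait forms its own family, while cortical surface area
and thickness are pooled into one family (same MRI measurement); the
pipeline further stratifies families by estimator so sensitivity analyses
do not dilute the primary IVW family.

# The synthetic generator

`simulate_gwas_pair()` draws, per SNP: MAF uniform on [0.1, 0.5];
gamma from N(0, 0.15) truncated below at 0.15; alpha per pleiotropy mode
(none / balanced / directional / correlated-with-strength, applied to a
configurable fraction of SNPs); observed effects with SE =
1/sqrt(2 MAF (1-MAF) N). Defaults mirror the emulated study's cohort
sizes: exposure GWAS N = 8293 (cytokine panel scale, SD units), outcome
N = 257,841 (cognitive performance scale), causal beta 0.1.

The lower truncation is one-sided, so all SNP-exposure effects are
positive — the effect allele is the exposure-increasing allele. This is
deliberate: with symmetric ± gamma, a mean-shifted alpha cancels in the
Wald ratios and "directional" pleiotropy would be undetectable by
construction; one-signed gamma is the canonical MR simulation convention
and makes the Egger intercept estimate the mean direct effect. The
truncation point guarantees instruments clear the relaxed selection
threshold at the default exposure sample size, so tests never face empty
instrument sets.

LD is emitted as a pairwise table (block-diagonal, configured r² within
blocks), not as correlated noise: the estimators assume independent
post-pruning instruments, as the emulated analysis does. Strand flips
complement both outcome alleles of a configurable fraction of
non-palindromic SNPs; palindromic SNPs get A/T or C/G pairs and are never
strand-flipped so the generating truth stays well defined. A z-only mode
omits beta/se from the outcome table, emulating GWAS releases that
publish only z and p.

What the generator does **not** emulate: winner's-curse selection of
instruments (effects are drawn, not discovered), sample overlap between
the two GWAS, population stratification, binary outcomes, indels or
multi-allelic sites, and realistic genome-wide LD structure. Passing
tests therefore demonstrate correctness of the estimators and plumbing
under the stated structural model, not robustness to everything real
summary statistics can contain.

# Validation scale and results

The test suite validates against hand-derived constants (a 3-SNP worked
fixture with ratios 0.2/0.25/0.2 and equal weights), independent oracles
(generic weighted least squares for IVW and Egger; exhaustive grid search
for the weighted median; brute-force step-up for BH), and Monte-Carlo
experiments at a scale chosen to keep the default run comfortably fast:
500 replicates of 50-SNP panels for IVW bias/coverage and for the
directional-pleiotropy behaviour of Egger and the weighted median; 200
replicates with 1000 parametric simulations each for the PRESSO null;
1000 replicates of small panels for the generator's SE calibration.

One caveat worth stating: under 30% one-sided contamination the weighted
median carries a small finite-sample bias (it sits at a shifted quantile
of the clean ratio distribution; the bias shrinks with instrument
strength, not with the number of SNPs). Averaged over replicates it stays
within two bootstrap SEs of the truth, which is the sense in which the
robustness claim is tested here; on a single dataset with heavy one-sided
contamination the weighted median should be read as bias-reduced, not
unbiased.

# Known limitations

Biallelic SNVs only; no proxy-SNP substitution for instruments missing
from the outcome GWAS; no binary-outcome power mode; no mode-based,
multivariable or contamination-mixture estimators; LD must be supplied as
a precomputed table (the package never computes it from genotypes). The
reverse analysis excludes SNPs shared by the configured trait pair at the
genome-wide threshold and deliberately offers no relaxed-threshold
fallback, mirroring the stricter convention for reverse-direction
instruments.
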