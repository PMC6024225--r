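---
title: "Methods: Mendelian randomization with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldmr)
```

# The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables: if a variant changes an exposure (say, a circulating hormone)
and affects a disease outcome only through that exposure, the ratio of its
outcome association to its exposure association estimates the causal
effect. Molecular exposures are often instrumented by fine-mapped variants
from one or two gene regions. Variants within a region are correlated
through linkage disequilibrium (LD), so the standard MR toolkit — which
assumes independent instruments — either discards most of the signal by
aggressive pruning or understates uncertainty by ignoring the correlation.
`ldmr` implements the correlated-instrument workflow end to end: reading
and harmonizing summary statistics and a signed LD matrix, variant-validity
QC, instrument selection, a generalized weighted regression estimator with
a full between-variant error covariance, principal-components
stabilization when that covariance is near-singular, odds-ratio reporting
with multiple-testing flags, cohort pooling, and power analysis.

# The estimator

With exposure associations $\hat\beta_{Xj}$, outcome associations
$\hat\beta_{Yj}$ (standard errors $\sigma_{Yj}$), and signed LD
correlations $\rho_{j_1 j_2}$, the model is the zero-intercept regression

$$\hat\beta_{Yj} = \theta\,\hat\beta_{Xj} + \varepsilon_j,\qquad
\operatorname{Var}(\varepsilon)=\Sigma,\qquad
\Sigma_{j_1 j_2} = \sigma_{Y j_1}\sigma_{Y j_2}\rho_{j_1 j_2},$$

fitted by generalized least squares:

$$\hat\theta = (X^\top\Sigma^{-1}X)^{-1}X^\top\Sigma^{-1}Y,\qquad
\operatorname{se}(\hat\theta) = (X^\top\Sigma^{-1}X)^{-1/2}.$$

This is equivalent to regressing the outcome on a weighted genetic score
built from the individual-level data, but needs only summary statistics.
Three structural facts anchor the implementation and its tests: with
$\rho = I$ the estimator collapses to the textbook inverse-variance
weighted formula; with a single variant it collapses to the Wald ratio
$\hat\beta_Y/\hat\beta_X$; and it is exactly invariant to re-coding the
effect allele of any variant (which negates $\hat\beta_{Xj}$,
$\hat\beta_{Yj}$ and the corresponding row and column of $\rho$
simultaneously).

Two conventions deserve emphasis:

* **Which standard errors enter $\Sigma$.** The package builds $\Sigma$
  from the *outcome* standard errors, the convention of the generalized
  IVW method for correlated variants. A `weights = "exposure_se"` switch
  exists purely for sensitivity analysis and announces itself when used.
* **Exposure-side uncertainty is ignored** (the first-order,
  "fixed-denominator" convention of summary-data MR). This is accurate
  when instruments are strong — per-variant F statistics well above 10 —
  and is the regime the defaults of the synthetic generator deliberately
  occupy (see below). With weak instruments the estimator inherits
  regression-dilution attenuation toward zero; the package does not
  correct for this, and users with weak instruments should interpret
  estimates accordingly.

The GLS solve goes through a Cholesky factorization of $\Sigma$; no
explicit inverse is ever formed. If $\Sigma$'s condition number exceeds
1e8 — the signature of variants in near-perfect LD — `ivw_correlated()`
refuses with an error that points to the stabilized estimator, and the
pipeline's `estimator = "auto"` mode performs that fallback itself.

# Principal-components stabilization

For a region whose LD matrix is near-singular, `pc_ivw()` forms the
weighted correlation matrix

$$\Psi_{j_1 j_2} = \frac{\hat\beta_{X j_1}\hat\beta_{X j_2}\,
\rho_{j_1 j_2}}{\sigma_{Y j_1}\sigma_{Y j_2}},$$

whose leading eigenvectors concentrate the exposure signal relative to the
outcome noise. The smallest number $k$ of leading components whose
eigenvalues sum to at least `variance_kept` (default 0.99) of the total is
retained; $X$, $Y$ and $\Sigma$ are projected through those eigenvectors
and the GLS formula is applied in the projected space. Numerical choices:
eigenvalues below `1e-10` of the largest are clamped to zero before the
cumulative-variance calculation (noisy external LD estimates can produce
small negative eigenvalues); `variance_kept = 1` on a full-rank input
reproduces `ivw_correlated()` exactly, because the projection is then
orthogonal; and a perfectly duplicated variant contributes a zero
eigenvalue, so the estimator returns the duplicate-free answer — both
properties are asserted in the test suite. An unweighted mode
(`weighted_psi = FALSE`) that decomposes $\rho$ itself is available for
sensitivity analysis.

# Harmonization and its defaults

`harmonize()` inner-joins exposure, outcome and LD on variant id and
re-anchors every effect direction to the exposure effect allele: swapped
(or strand-complement-swapped) outcome alleles negate
$\hat\beta_Y$ and reflect the allele frequency; LD signs are re-anchored
through the matrix's recorded reference alleles. Palindromic variants
(A/T, C/G) carry no strand information in their labels, so they are
oriented by allele frequency when it is informative and dropped — with a
logged reason — when the minor allele frequency in either dataset lies
within 0.08 of 0.5 or is missing. The 0.08 band is the conservative
default of two-sample MR practice rather than a number with special
status; it is an argument (`palindromic_eaf_band`), every drop is logged,
and users who prefer a different policy can reproduce it exactly. Variants
whose allele pairs cannot be reconciled at all are dropped and logged.
Harmonizing an already-consistent pair changes nothing, so the operation
is idempotent.

LD matrices are validated on read: asymmetry up to 1e-6 is symmetrized as
$(M + M^\top)/2$ and anything larger is an error, as is a diagonal entry
off 1 by more than 1e-6; entries slightly outside $[-1, 1]$ are clipped.
These tolerances are fixed so that a given file always parses to the same
matrix.

# QC and instrument selection

`apply_qc_filters()` drops variants with minor allele frequency below
0.01, call rate below 95%, Hardy–Weinberg equilibrium p below 0.001
(one-degree-of-freedom chi-square goodness-of-fit; the well-powered regime
these thresholds operate in does not need an exact test), or imputation
info score below 0.6. All comparisons are strict, so boundary values
survive. A missing info score is treated as 1 (directly genotyped) with a
warning, so the imputation filter never silently removes typed variants;
criteria whose inputs are absent are skipped per-variant with a warning.
When a variant fails several criteria the recorded reason is the first in
the fixed order maf, call_rate, hwe, info, which makes QC reports
deterministic. `confounder_filter()` screens instruments against a table
of association p-values with potential confounders (education, deprivation
index, alcohol, smoking, …) at the Bonferroni threshold
$\alpha / (\text{variants} \times \text{traits})$ — the denominator is
logged so the correction is auditable.

`stepwise_select()` visits variants by ascending exposure p-value and
keeps a candidate only if its squared correlation with *every* variant
already kept is below `r2_max` (default 0.4). Pruning against all
previously selected variants (not only the first) is what guarantees the
selected set has low pairwise correlations throughout. Ties in p-value
break by genomic position, then variant id, so selection is deterministic;
r² is the square of the signed r, so allele orientation cannot change the
outcome. `conditional_select()` supports the alternative design in which
the instrument list comes from a prior conditional analysis: it returns
the sublist present in the data, in list order, reporting absentees —
different outcome datasets typically have different subsets available.

# Reporting

`to_odds_ratio()` exponentiates a log-odds estimate into an odds ratio per
unit increase in the exposure; for 95% intervals the normal quantile is
fixed at 1.959964 so printed intervals round-trip bit-stably.
`meta_fixed_effect()` pools cohort estimates with inverse-variance weights
$w_i = \mathrm{se}_i^{-2}$ — the natural reading of a combined-cohorts
row in a results table, though pooling at the variant level (harmonizing
pooled inputs) is equally supported by running the pipeline on a combined
dataset, and the two need not agree exactly. `flag_significance()` marks
estimates `corrected` below $\alpha/m$ and `nominal` below $\alpha$; the
family count $m$ (default 7: two disease outcomes, four classes of
cardiovascular risk factors, male pattern balding) is a configuration
value, not a constant, because what constitutes a family is a
study-specific judgement.

# Power

For a binary outcome with case fraction $K$, outcome sample size $n$, and
instruments explaining $r^2_{GX}$ of the exposure variance, the power of a
two-sided level-$\alpha$ test against a true log odds ratio $\theta$ per
SD of exposure is approximated by

$$\text{power} = \Phi\!\left(|\theta|\sqrt{n\,r^2_{GX}\,K(1-K)} -
z_{1-\alpha/2}\right),$$

dropping the $K(1-K)$ factor for continuous outcomes in SD units. This is
the standard normal-approximation implemented by the online calculators
used for summary-data MR; the one-tailed form means power at $\theta = 0$
is $\alpha/2$, a documented property of the convention rather than a bug.
The formula is printed here precisely so users can compare against any
other calculator. The test suite verifies it against simulation-based
rejection rates obtained by running the full generator-plus-estimator
chain on matched single-instrument scenarios — an independent route to the
same quantity.

# The synthetic generator and what it does (not) show

`simulate_summary_pair()` draws
$\hat\beta_X \sim \mathrm{MVN}(\beta_X, D_X \rho D_X)$ and, independently,
$\hat\beta_Y \sim \mathrm{MVN}(\theta\beta_X + \text{pleiotropy},
D_Y \rho D_Y)$, with $D$ diagonal matrices of standard errors — the
minimal generative model consistent with the estimator's own assumptions
(two-sample independence, MVN sampling noise with covariance
$\mathrm{se}\cdot\rho\cdot\mathrm{se}$). Summary-level simulation keeps
every test sub-second per replicate; no genotypes are ever simulated.

Defaults, chosen once as a realistic single-region scenario:

* `n_variants = 20`, AR(1) LD with neighbour correlation 0.5 (`"identity"`
  and constant-correlation `"blocks"` structures are available; all are
  positive-definite by construction for $|\rho| < 1$).
* `beta_x_true`: a fixed pattern of per-allele effects with magnitudes
  0.03–0.09 on a log-transformed exposure, sized so the region explains
  on the order of 1–3% of exposure variance — the scale of a fine-mapped
  hormone locus.
* `se_x = 0.002`: exposure associations measured at biobank scale
  (effective n around 6×10⁵), i.e. per-variant instrument F statistics in
  the hundreds. This places the generator in the strong-instrument regime
  where the estimator's fixed-denominator standard errors are valid; it is
  a model assumption, not an incidental choice. With noisier exposure
  associations (an exposure GWAS of a few thousand, se_x ≈ 0.03) the same
  machinery exhibits the expected regression-dilution attenuation of a
  percent or two at $\theta = 0.2$ — simulate it with `se_x = 0.03` to see
  the size of the effect. Type-I error under $\theta = 0$ is unaffected,
  because conditional on the exposure draws the estimate is exactly
  mean-zero normal with the model's standard error.
* `se_y = 0.02`: a large binary-outcome GWAS (log-odds scale).
* One master seed; every quantity derived from a configuration is
  bit-reproducible given that seed. Replicated studies
  (`run_simulation_study()`) derive per-replicate seeds from a stream
  seeded by the master seed, so studies with different seeds share no
  replicates and replicate streams are mutually independent.

What passing calibration tests on this generator demonstrates: the
estimator's algebra, its standard errors, and its type-I error and
coverage are correct *under the model it assumes*. What they do not
demonstrate: robustness to features real data have and the model lacks —
LD matrices estimated in a mismatched reference panel, winner's curse in
the exposure associations, weak instruments, participant overlap between
samples, or horizontal pleiotropy. The last is deliberate: the design
relies on gene-region specificity for exclusion-restriction, not on
pleiotropy-robust estimation, and the test suite asserts that directional
pleiotropy under a null causal effect *does* inflate rejection rates —
the estimator is documented as non-robust rather than pretending
otherwise.

# Simulation sizes and numerical conventions

The shipped calibration studies use 2000 replicates for type-I error
(binomial Monte-Carlo band [0.035, 0.065] at $\alpha = 0.05$), 1000 for
coverage ([0.93, 0.97]) and bias (3 Monte-Carlo-se band), and 5000 for
each power spot-check (tolerance ±0.02) — sizes at which the Monte-Carlo
bands are meaningfully tighter than the effects they guard against while
keeping the whole suite around two minutes. Other fixed conventions:
condition-number gate 1e8 on $\Sigma$; eigenvalue clamp at 1e-10 of the
largest in `pc_ivw()`; LD read tolerances 1e-6 (symmetrization and
diagonal); palindromic frequency band 0.08; z-quantile 1.959964 for 95%
intervals; strict inequalities at every QC threshold; numeric output
printed at 17 significant digits so reports and round-trips are
byte-stable.

# Known limitations

* No weak-instrument correction and no pleiotropy-robust estimators
  (MR-Egger, weighted median/mode) — out of scope by design.
* No heterogeneity decomposition across variants.
* The LD matrix is taken as known; uncertainty in externally estimated
  correlations propagates only through the eigenvalue clamp, not into
  standard errors.
* Fixed-effect pooling assumes cohorts estimate one common parameter;
  between-cohort heterogeneity is not modelled.
* Sex-chromosome variants and multi-allelic sites are not handled;
  variant ids are the only join key (no liftover, no position matching).
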