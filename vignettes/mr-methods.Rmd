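---
title: "Two-sample and multivariable MR in mrpath: models, diagnostics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and multivariable MR in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The estimation model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure. For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be
its association with the exposure in one GWAS and $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$) its association with the outcome in another. Each SNP
contributes a Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$; exposure-side uncertainty
is ignored both here and in the weights below, the standard two-sample
convention (`wald_ratio()` documents this and the tests verify the
algebraic identity between the two formulations).

The inverse-variance-weighted (IVW) estimate is the weighted regression of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with weights
$w_j = 1/\sigma_{Yj}^2$:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
{\sum_j w_j \hat\beta_{Xj}^2}.$$

Constraining the intercept to zero assumes no directional horizontal
pleiotropy. MR-Egger frees the intercept: the intercept then estimates the
average direct (pleiotropic) SNP effect on the outcome and the slope is a
pleiotropy-adjusted causal estimate. Because Egger's estimand depends on
how alleles are oriented, `mr_egger()` first orients every exposure beta
non-negative (flipping the paired outcome beta); the fitted line is
invariant to any further sign flips, which the tests assert.

Multivariable IVW (`mr_mvmr_ivw()`) regresses $\hat\beta_{Yj}$ jointly on
two exposures' beta columns without an intercept, again weighted by
$1/\sigma_{Yj}^2$. Each coefficient is a *direct* effect: the effect of
that exposure with the other held fixed. The fit is by explicit normal
equations; `lm()` serves as an independent oracle in the test suite, never
as the implementation.

### Standard errors, intervals, p-values

The package defaults to multiplicative random-effects standard errors:
the fixed-effect SE is scaled by the residual standard deviation of the
weighted regression, floored at 1 so apparent underdispersion never
tightens an interval. The reasoning: heterogeneity among per-SNP
estimates is the rule in applications of this design, and fixed-effect
SEs are then anti-conservative; the point estimate is identical under
both weightings (a tested invariant), so only interval width is at stake.
Fixed-effect SEs remain available via `weights_model = "fixed"`.
Intervals are $\hat\theta \pm 1.96\,\mathrm{SE}$ (normal quantile, no
t-correction) and p-values are two-sided normal — deliberately simple
constants so any reported number can be reproduced exactly from beta and
SE. For binary outcomes `to_odds_scale()` exponentiates the estimate and
bounds, reporting percent-lower-odds text rounded to the nearest integer
while the underlying columns keep full precision.

## Harmonization rules

`harmonize_pair()` aligns an outcome table to the exposure's effect
alleles: identical alleles are copied; swapped alleles negate the outcome
beta and reflect the EAF; alleles that match only after complementing are
treated as opposite-strand reports (attempted only after direct and
swapped matching fail, which minimizes spurious complement matches).
Palindromic SNPs (A/T, C/G) cannot be oriented from letters. Under the
default `drop_ambiguous` policy a palindromic SNP is dropped whenever
either trait's EAF lies inside the ambiguity band (default 0.42-0.58,
where frequency is uninformative about strand) or is missing; otherwise
the row is aligned by EAF concordance. The `infer_by_eaf` policy always
aligns by concordance and treats a missing EAF as a hard error naming the
SNP — missing frequencies are never imputed. Every input row is accounted
for: retained + dropped + missing-from-outcome equals the instrument
count, and the test suite checks the full enumeration of biallelic
configurations against an independently coded rule table.

Greedy clumping (`greedy_clump()`) keeps the smallest-p SNP, removes
neighbours within 10 Mb at $r^2 \ge 0.01$ (both configurable), and
repeats; p-value ties break by genomic coordinate so results are
order-independent. Published lead-SNP lists are already approximately
independent, so with no LD information the table passes through unchanged
with a logged notice; an LD pair missing from a supplied pair list is an
error, never an assumption of independence.

For multivariable analysis `build_mvmr_dataset()` unions the two
instrument lists (counting the overlap), clumps, requires an association
of every retained SNP with *both* exposures, and harmonizes everything to
the first exposure's effect alleles. The univariable disease analyses
deliberately retain instruments shared between the exposure GWAS — the
point of those analyses is to show what a typical single-exposure study
would report — while the exposure-on-exposure (bidirectional) analysis
excludes them, since a shared instrument cannot arbitrate direction.
These per-analysis defaults are pinned in `run_ad_analysis()` and
`run_bidirectional()` rather than being a global switch.

## Diagnostics

* **Steiger filtering** compares the variance a SNP explains in the
  exposure and in the outcome (default `eaf_beta`:
  $2f(1-f)\beta^2$ for SD-unit traits; `t_stat`:
  $t^2/(t^2+n-2)$ as fallback). Filtering uses the plain comparison, not
  a significance threshold: an instrument explaining more outcome than
  exposure variance contradicts the assumed direction regardless of
  significance. The Steiger z test on Fisher-transformed correlations is
  computed for reporting.
* **Cochran's Q** uses first-order Wald-ratio variances, matching the IVW
  weighting dialect, with a $\chi^2_{k-1}$ reference; its type-I error
  calibration under a homogeneous null is a tested property.
* **F statistic**: $F = \frac{R^2}{1-R^2}\cdot\frac{n-1-k}{k}$, flagged
  weak at $F \le 10$. The conditional instrument strength for
  multivariable MR in a two/three-sample design is not computable from
  these inputs and is intentionally not offered.
* **Leave-one-out** refits IVW per omission and flags shifts larger than
  one full-sample SE (configurable) or sign changes — a reproducible
  numeric proxy for the usual visual distortion check.
* **Funnel data** pairs each Wald ratio with its precision; asymmetry is
  summarized by a precision-weighted regression of estimate on precision
  (slope near zero indicates symmetry). With one SNP the summary is
  reported as undefined rather than omitted.

## The synthetic GWAS generator

`scenario_config()` encodes the causal structures that make univariable
MR of two correlated exposures ambiguous: confounding of one exposure by
the other (a/b), full mediation (c/d), horizontal pleiotropy through the
other exposure (e/f), balanced direct SNP-outcome pleiotropy (g), and
joint direct effects with a bidirectional exposure relationship (h).
Genotypes are independent Binomial(2, MAF) draws — the post-clumping
regime the estimators see; exposures are linear structural equations
normalized to unit variance (genetic + upstream + confounder + residual;
an over-committed budget is an error listing the contributions), so all
coefficients are in SD units; the disease is Bernoulli from a logistic
model with intercept `qlogis(ad_base_prevalence)`.

Choices a reader should know about:

* **Two-stage bidirectionality.** A simultaneous causal loop has no
  unique simulation without an equilibrium convention, so reciprocal
  arrows are realized in a documented assignment order: the first trait
  is drawn, the second depends on it, and a feedback coefficient adds the
  second back onto the first, rescaled to unit variance. Ground-truth
  totals (`ground_truth()`) are path-traced under exactly this
  realization.
* **Non-overlapping samples.** Each exposure's GWAS runs in its own
  simulated sample and the disease GWAS in a third, so cross-trait
  estimation errors are independent — the clean two-sample setting. (Real
  exposure GWAS of correlated traits often share participants; that bias
  mechanism is deliberately outside the generator.)
* **Selection and winner's curse.** Instruments are whatever SNPs pass
  `p_threshold` in their discovery sample, so instrument counts vary by
  replicate, instrument lists can overlap exactly as published lead-SNP
  lists do, and selected effect sizes are optimistically biased. The
  desk-scale defaults — 100 candidate SNPs per exposure explaining 10% of
  variance, 20 000 individuals per sample, selection at 1e-4 — are a
  scaled-down analogue of a consortium GWAS with genome-wide selection at
  5e-8; tests that specifically need the strong-instrument regime use
  5e-8 with larger per-SNP effects and say so.
* **Directional pleiotropy is oriented.** `pleiotropy_mean` is the mean
  direct outcome effect of the exposure-raising allele. Attaching a mean
  effect to arbitrary allele labels would cancel under orientation and no
  estimator could detect it, so that construction is not offered.
* **Binary GWAS estimator.** Per-SNP log odds ratios default to the
  one-step score estimator ($\hat\beta = U/I$ with null score and
  information), which is vectorized across SNPs and accurate to third
  order in the effect size; per-SNP effects in these designs are ~0.02 or
  smaller, where the difference from the logistic MLE is far below
  estimation noise. Full per-SNP `glm` logistic regression is available
  (`method = "logistic"`) and is the oracle the score path is tested
  against.
* **Scenario magnitudes are conventions.** The diagrams being emulated
  are qualitative, so default path coefficients are fixed once at
  field-plausible values — exposure-on-exposure 0.5 SD/SD, direct disease
  effects of -0.2 and -0.3 (scenario c: -0.4) log-odds per SD, cross
  pleiotropy explaining 5% of the other exposure, balanced pleiotropy SD
  0.05 — and are not tuned per analysis. Scenario (g) is realized with
  per-SNP direct disease effects independent of the exposure effects
  (balanced pleiotropy): under that realization both univariable and
  multivariable estimates are null in expectation. A variant in which
  pleiotropy is correlated with instrument strength would instead bias
  both analyses — that variant is representable via `pleiotropy_mean`
  but is not what (g) asserts.
* **Scenario (a) is intentionally ill-posed for MVMR.** When every
  instrument affects the first exposure only through the second, the two
  true exposure-beta columns are exactly proportional and the
  multivariable design is only identified through estimation noise.
  Estimates then carry an attenuation-induced split between the two
  collinear columns and their standard errors grow accordingly. The
  scenario is kept in the validation suite precisely because it shows
  what multivariable MR does at the edge of identifiability; its
  coverage enters the pooled coverage check rather than being asserted
  cell by cell.

What the generator does **not** emulate: linkage disequilibrium between
instruments, population stratification, sample overlap between exposure
and outcome GWAS, survival/attrition, assortative mating, and
non-collapsibility-free outcome scales. Logistic non-collapsibility
attenuates realized disease log-odds slightly relative to the structural
coefficients (under 5% at the default effect sizes); parameter-recovery
checks therefore use Monte-Carlo error bands rather than exact equality.
Passing tests show the estimators recover the parameters of *this*
generative law; they cannot certify robustness to the listed departures.

## Numerical choices

Weighted least squares is solved by explicit normal equations with a
condition-number guard (error above 1e10, reported); an exposure column
that is identically zero is dropped from the multivariable fit with a
warning — the remaining coefficient then reduces exactly to univariable
IVW, a tested identity — while non-trivial collinearity (e.g. duplicated
exposures) always errors rather than silently splitting an effect.
Deterministic per-SNP regressions floor SEs and p-values at 1e-300 to
stay inside their open domains. Clumping ties break by (chrom, pos).
All randomness flows through explicit integer seeds; the same
configuration and seed reproduce byte-identical outputs, which the
pipeline tests assert.

## Problem sizes used by the test suite

Unit tests run on toy tables (3-200 SNPs). Parameter-recovery tests use
single simulated studies of 20 000-50 000 individuals per sample. The
scenario-recovery study runs scenarios a, c, g and h at the generator
defaults for 200 replicates each, checking the qualitative verdict table
and pooled 95% CI coverage of the true direct effects; calibration
properties (Q type-I error, GWAS p-value uniformity) use 1000-1500
replicates of summary-level draws. These sizes were chosen so Monte-Carlo
error is small relative to the asserted margins.

## Limitations

The package analyzes summary statistics only; it neither computes GWAS
from raw genotypes at scale nor queries LD reference panels (proxy SNPs
must arrive pre-substituted, LD arrives as an explicit table). Estimators
beyond those above — weighted median/mode, outlier-removal methods — are
out of scope, as is any multiple-testing adjustment (unadjusted intervals
are reported by design). Reported odds ratios carry the usual
non-collapsibility caveat of logistic-scale MR. The published per-SNP
instrument tables of the motivating application are journal supplementary
material and are not redistributed; the reproduction test documents the
expected file layout under `inst/extdata/study/` and runs whenever those
files are supplied.
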