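---
title: "Methods: two-sample MR for gut microbiome exposures with protein mediation"
author: "gutmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for gut microbiome exposures with protein mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmr)
```

## The question and the design

Gut microbiome composition is associated with chronic kidney disease (CKD) in
observational cohorts, but confounding (diet, medication, reverse causation
through uremia) makes those associations hard to interpret. Two-sample
Mendelian randomization (MR) sidesteps part of the problem: genetic variants
associated with the abundance of a microbial feature are fixed at conception,
so — under the instrumental-variable assumptions — the association between
those variants and CKD in an independent cohort estimates a causal effect of
the feature on disease.

`gutmr` implements the full chain for this design at summary-statistics
level: a quantitative exposure GWAS of microbial features (abundances in SD
units, cohorts of ~1,500 individuals in the motivating setting), a
case-control outcome GWAS on the log-odds scale with severe case/control
imbalance (hundreds of cases against tens of thousands of controls), and an
optional quantitative mediator GWAS (serum protein levels) for two-step
mediation. Three phases mirror the study design the package targets:

1. **Screening** — every microbial feature against the primary CKD outcome;
2. **Replication** — hits re-estimated against independent outcome GWAS;
3. **Mediation** — two-step MR through candidate serum proteins.

## Instruments

Variants are selected at the locus-wide threshold `p < 1e-5` — the
convention in microbiome MR, where genome-wide significant loci are too few —
with a minor-allele-frequency filter `min(EAF, 1 - EAF) > 0.01`. The
frequency filter is deliberately interpreted in the minor-allele sense: a
0.995-frequency effect allele has a rare minor allele and is excluded, which
a literal `EAF > 0.01` would not do. Independence is enforced by greedy LD
clumping: repeatedly take the remaining variant with the smallest p-value and
prune everything within ±1000 kb at r² ≥ 0.1. Greedy index-SNP clumping is
standard practice (it is what PLINK-style clumping does); the tests verify
that its output is always one of the maximal valid subsets by brute-force
enumeration on small instances. LD enters only as a precomputed r² table —
the package never touches genotypes — and pairs missing from the table are
treated as unlinked.

Instrument strength uses the standard variance-explained form

$$R^2 = \frac{2\beta^2\,\mathrm{EAF}(1-\mathrm{EAF})}
{2\beta^2\,\mathrm{EAF}(1-\mathrm{EAF}) + 2N\,\mathrm{SE}^2\,\mathrm{EAF}(1-\mathrm{EAF})},
\qquad F = \frac{(N-2)\,R^2}{1-R^2},$$

with the usual `F > 10` convention for acceptable weak-instrument bias;
`strength_summary()` raises a flag when any instrument falls below it.
Exposures with fewer than 3 harmonized instruments are excluded from
estimation.

## Harmonization

Outcome records are aligned to the exposure's effect allele: swapped alleles
negate the outcome beta and complement its frequency; strand complements are
flipped first. Palindromic variants (A/T, C/G) cannot be strand-resolved from
alleles alone. The default mode drops them when the minor-allele frequency is
0.42 or above in either dataset (frequency too close to 0.5 to trust) and
orients the remainder by effect-allele-frequency agreement; a strict mode
drops all palindromes. Irreconcilable allele sets are dropped, never guessed,
and every disposition is logged per SNP.

Variants absent from the outcome may be replaced by a proxy at r² > 0.8.
Because the LD table stores r² only, the phase between query and proxy
alleles is unknowable; orientation is inferred from allele-frequency
similarity, and proxies whose two orientations are not clearly
distinguishable (frequency difference under 0.05) are dropped. This is a
real limitation of r²-only references and is surfaced in the disposition
log rather than hidden.

## Estimators

All estimators consume the harmonized set $(\hat\beta_{Xj}, \hat\beta_{Yj},
\sigma_{Yj})$ and are authored in closed form (the test suite checks them to
1e-10 against a brute-force weighted-least-squares oracle).

**IVW.** Weighted regression of outcome on exposure effects through the
origin, weights $1/\sigma_{Yj}^2$:
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$. The fixed-effect SE is $(\sum w_j\hat\beta_{Xj}^2)^{-1/2}$;
the default multiplicative random-effects model inflates it by
$\max\{1, \sqrt{Q/(J-1)}\}$, i.e. it widens under heterogeneity but never
narrows under under-dispersion. A consequence worth stating plainly: under
exact homogeneity the floored test is conservative by construction (the floor
binds about half the time), so calibration claims about "the IVW test" are
assessed on the fixed-effect z-test, which is exactly calibrated; the
random-effects test is verified to be no more liberal. Both models are
reported and the choice is logged per run.

**MR-Egger.** Instruments are oriented so the exposure effect is positive,
then outcome effects are regressed on exposure effects with a free intercept
(weights $1/\sigma_{Yj}^2$). The slope is the pleiotropy-adjusted causal
estimate under InSiDE; the intercept estimates average directional
pleiotropy. Both use t-tests with $J-2$ df from the standard weighted
least-squares variance — no floor, so the intercept test is exactly
calibrated. MR-Egger's power is governed by the spread of instrument
strengths: when all instruments sit just above the selection threshold (the
typical situation with `p < 1e-5` selection in a 1,539-person GWAS), oriented
exposure effects vary little, the intercept SE approaches the per-SNP outcome
SE, and detection power for modest pleiotropy (about 2 outcome-SEs) is low.
The calibration harness quantifies this honestly rather than assuming the
textbook large-spread regime.

**Weighted median.** Wald ratios $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ are
ordered with normalized weights $w_j \propto (\hat\beta_{Xj}/\sigma_{Yj})^2$;
cumulative midpoints $p_j = S_j - w_j/2$ are linearly interpolated at
$p = 0.5$. The estimate is consistent when valid instruments carry more than
half the weight. Its SE comes from a parametric bootstrap (both betas
resampled from normals with their SEs; explicit seed; default 1000
replicates) and the p-value from a normal approximation. Two finite-sample
properties are documented rather than patched: (i) the bootstrap variance of
a median-type functional is biased upward at J around 20, so the test is
mildly conservative; (ii) under directional pleiotropy carried by a fraction
$c < 0.5$ of instruments, the population weighted median sits at the
$0.5/(1-c)$ quantile of the valid-ratio distribution, so the estimator is
*less* biased than IVW but not unbiased at realistic per-SNP noise — its
headline robustness is exact only in the small-noise limit.

## Sensitivity analysis

**Cochran's Q** on the Wald ratios with NOME weights
($w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$), chi-square with $J-1$ df.
**Leave-one-out** IVW re-estimates with the full-set estimate as a reference
row. **Funnel coordinates** (ratio vs precision $|\hat\beta_{Xj}|/\sigma_{Yj}$)
are emitted as numbers; plotting is left to `plot(fit, which = "funnel")`.

**MR-PRESSO.** The observed residual sum of squares
$\mathrm{RSS} = \sum_j w_j(\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$
(leave-one-out IVW slopes) is referred to a null distribution built by
simulating outcome effects from $N(\hat\theta_{(-j)}\hat\beta_{Xj},
\sigma_{Yj})$, 1000 draws by default. Empirical p-values carry an add-one
pseudo-count so finite simulation never reports zero. Per-SNP outlier
p-values come from each SNP's own simulated residual distribution with
Bonferroni correction across instruments; the distortion test compares the
observed shift between the all-SNP and outlier-removed IVW estimates with
the shifts produced by removing random same-sized non-outlier sets. The
corrected estimate is plain IVW on the unflagged instruments (the tests
verify this consistency exactly), absent when no or all SNPs are flagged.
The distortion sub-seed derives deterministically from the master seed.

## Mediation

Two-step MR with the product-of-coefficients decomposition: indirect effect
$\beta_1\beta_2$ (exposure→mediator times mediator→outcome), proportion
mediated $\beta_1\beta_2/\beta_3$ against the total effect $\beta_3$. The
three inputs are MR estimates from non-overlapping cohorts, so the bootstrap
is parametric over the estimate triplet — independent normal draws around
each point estimate — rather than a resampling of SNPs; independence of the
three estimates is an assumption worth remembering when cohorts overlap.
Percentile 2.5/97.5 intervals and a sign-test p-value (add-one corrected)
summarize the draws; draws whose total effect is numerically zero are
discarded and counted, and more than 50% discarded is a hard error.
Proportions outside [0, 1] are reported as computed with a qualitative flag —
inconsistent mediation is information, not an error. Percentile intervals
for this ratio functional are slightly conservative when the total-effect
estimate is noisy (z below about 3) and approach nominal coverage as
precision grows; the calibration study quantifies this. `mediation_screen()`
computes mediation only for triplets whose three links all pass the
screening level, logging every skip.

## The synthetic-data generator

`simulate_study()` emulates the study design, not any particular dataset:

* exposure GWAS of n = 1539 with effect-allele frequencies uniform on
  (0.05, 0.95) and SEs $1/\sqrt{2n\,\mathrm{EAF}(1-\mathrm{EAF})}$;
* instrument effects drawn from $N(0, \gamma_{sd}^2)$ *conditional on
  reaching* `p < 1e-5`, sampled exactly by inverse CDF on the truncated tail
  (the distribution rejection sampling converges to, at O(1) cost). The
  default `gamma_sd = 0.12` puts selected F-statistics mostly between 20 and
  40 with none below 10 — the instrument-strength profile of a locus-wide
  threshold in a 1,539-person GWAS, where selection rather than the effect
  scale dominates;
* a binary outcome with 489 cases and 75,531 controls represented through
  the effective sample size $4/(1/\text{cases} + 1/\text{controls})$ — the
  standard device for extreme imbalance without simulating logistic fits;
* 20 instruments per feature by default (the motivating studies range from
  3 to 40, with key taxa at 11 and 18);
* pleiotropy modes `none`, `balanced`, `directional`, `inside-violating`,
  applied to a configurable fraction of instruments and anchored to the
  exposure-increasing allele — a "directional" shift defined against
  arbitrary allele coding would cancel in ratio space and bias nothing;
* optional per-SNP contamination in units of the outcome SE (same
  anchoring), block-exchangeable LD for exercising clumping and proxies,
  an optional mediator chain with its own instruments, and a `noise_free`
  switch under which IVW recovers the true effect to machine precision.

Exposure betas are the true instrument effects: the reported exposure SE
describes the emulated GWAS, but no estimation noise is added on the
exposure side. This keeps the estimators exactly unbiased with valid
instruments (the property the calibration studies measure) at the price of
not emulating winner's curse; a generator that selects on noisy observed
effects would attenuate all estimates by roughly
$\gamma_{sd}^2/(\gamma_{sd}^2 + \mathrm{SE}^2)$ and make the calibration
targets unreachable by construction. The generator also does not attempt
real LD maps, realistic allele-frequency spectra, or the compositional
structure of microbiome abundances — passing tests say the *estimators*
behave as specified under the stated model, not that real data meet the
model.

## Numerical and design choices

* Ties everywhere break deterministically: ascending p-value, then rsid.
* All randomness flows from explicit seed arguments through a private RNG
  stream; the caller's `.Random.seed` is never touched, and sub-seeds derive
  from the master seed by a fixed integer map.
* Empirical p-values use add-one pseudo-counts; stored p-values are floored
  at 1e-300 to respect the (0, 1] contract under extreme z.
* Screening uses nominal two-sided α = 0.05, mirroring practice in this
  literature; Bonferroni and Benjamini–Hochberg adjusted p-values are
  reported alongside, not used for gating.
* Report tables are byte-stable (fixed column order, `%.6g`, fixed sort, no
  timestamps), so identical configurations produce identical bundles.
* Calibration studies in the test suite use 2,000 null replicates for
  type-I error, 500 for the pleiotropy/outlier power studies and 1,000 runs
  for mediation coverage — sizes at which exact binomial intervals are tight
  enough to be informative while the whole suite stays quick on one core.

## Known limitations

* No Steiger directionality filtering, no mode-based estimation, no
  multivariable MR, and no reverse-direction analysis: out of scope by
  design.
* Proxy orientation from allele frequency alone fails for variants near 50%
  frequency; such proxies are dropped.
* The weighted-median significance test is conservative at typical
  instrument counts, and MR-Egger is underpowered when instrument strengths
  are homogeneous; both are properties of the published methods, reproduced
  faithfully and quantified by `calibration_report()`.
* Genome builds are treated as opaque: positions are compared only within a
  run, and nothing is lifted over.
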