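---
title: "BMI-stratified case-control association analysis with bmistrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BMI-stratified case-control association analysis with bmistrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmistrat)
```

## The scientific problem

Type 2 diabetes cases are clinically heterogeneous, and body mass index is
the strongest known risk factor. Stratifying cases into lean
(BMI < 25 kg/m²) and obese (BMI ≥ 30 kg/m²) subgroups — while comparing
each against one large, *unstratified* control pool — can expose risk
variants whose effects differ by adiposity, and can show whether lean cases
carry a disproportionate load of known risk alleles. `bmistrat` implements
this whole workflow as reusable, tested components: a cohort simulator with
BMI-modified genetic effects, per-study stratified association scans with
the standard QC filters and genomic control, inverse-variance
meta-analysis with stratum heterogeneity tests, a case-only
genotype-to-BMI scan, a binomial sign-enrichment test across known loci,
and weighted genetic risk scores with per-quintile odds ratios.

Individual-level cohorts of the size such studies use are not publicly
available, so the simulator is a first-class component: every downstream
stage is exercised and validated on synthetic data with the same
statistical structure.

## The generative model

For individual $i$ and variant $j$ with effect allele frequency $f_j$:

$$g_{ij} \sim \mathrm{Binomial}(2, f_j) \quad \text{(Hardy–Weinberg)}$$
$$b_i = \mu + \textstyle\sum_j a_j g_{ij} + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0, \sigma^2)$$
$$\operatorname{logit} P(D_i = 1) =
  \alpha + \textstyle\sum_j (\beta_j + \delta_j z_i)\, g_{ij} + \gamma z_i,
  \qquad z_i = (b_i - \mu)/\sigma$$

* $\beta_j$ is the per-allele log-odds ratio at mean BMI;
* $\delta_j$ is the *effect modification*: the change in the per-allele
  log-OR per standard deviation of BMI. A negative $\delta_j$ makes the
  allele's effect larger in lean individuals, which after ascertainment
  enriches lean cases for the risk allele — the phenomenon the stratified
  design is built to detect. Modification is continuous in standardized
  BMI rather than a step at the 25/30 cut-offs: the strata then
  *discretize* smooth heterogeneity, matching how the clinical cut-offs
  are applied to a continuous trait.
* $a_j$ (kg/m² per allele) models loci whose primary effect is on BMI
  itself (FTO/MC4R-like); such loci confound case-control comparisons in
  BMI-defined strata, which is why the package also provides the case-only
  scan.
* $\gamma$ is the log-odds of disease per SD of BMI (obesity as an
  environmental/physiological risk factor).

Defaults $\mu = 27$, $\sigma = 4.5$ kg/m² keep both the lean and the obese
tail well populated (about 33% and 25% of the population); BMI is kept
Gaussian — real BMI is right-skewed, but no tested contract depends on the
third moment. $\gamma = 0.3$ and a target prevalence of 10% are
conventional values for a middle-aged European-ancestry cohort; the
studies this design mimics did not publish cohort prevalences, so these
are the package's own defaults, stated here once and used everywhere.

**Intercept calibration.** $\alpha$ is found by bisection so that the
Monte-Carlo expected prevalence (200,000 draws from a dedicated,
seed-derived substream) matches the target within 0.2 percentage points.
Only variants with non-zero $\beta_j$, $\delta_j$ or $a_j$ enter the
draw — null variants cannot move the linear predictor — which keeps
calibration cheap for large null panels.

**Imputation quality.** A variant with info score $r_j < 1$ stores the
true genotype plus Gaussian noise of variance $(1 - r_j)\,2f_j(1-f_j)$
(the variance-ratio convention), truncated to $[0, 2]$. Disease and BMI
are always generated from the *true* genotypes, so low-info variants show
attenuated association — the behaviour imputed data actually has. Two
consequences of the truncation are worth knowing: the dosage variance is
slightly below the untruncated value, and the mean dosage is biased
towards 1 (upward for EAF < 0.5), so EAF estimates from very noisy
dosages are mildly biased. Neither affects variants passing the default
info > 0.5 filter materially.

**Randomness.** Every stochastic stage draws from a named substream
(`variants`, `calibrate`, `genotypes`, `bmi`, `status`, `dosage_noise`,
`ascertainment`) derived deterministically from one master seed, so
results are reproducible and adding a stage never perturbs another
stage's draws.

## Ascertainment and the shared control pool

`ascertain_study()` draws lean cases, obese cases and controls without
replacement. By default controls are *all* non-cases, not screened on BMI,
and the identical control set serves both strata — the design that
maximizes power and control allele-frequency precision. The
`stratify_controls` option instead restricts controls to BMI < 25 /
BMI ≥ 30 per stratum (the sensitivity design).

The shared pool has a statistical cost: the lean and obese effect
estimates are positively correlated, because they share the control
allele-frequency noise. The naive heterogeneity z-test
(`stratum_heterogeneity_test()`), which assumes independent estimates,
is therefore *mis-calibrated* under the shared-control design — in the
package's simulations its null variance is about 0.85 rather than 1, i.e.
it is conservative for the no-interaction null. The test suite
demonstrates this by comparing shared against independent control sets.
For inference about effect modification prefer the case-only scan
(`case_only_bmi_scan()`), which uses no controls at all, or the
case-versus-case score model (`score_case_vs_case()`).

## Association scans and genomic control

`run_stratified_gwas()` fits the additive logistic model per variant
(maximum likelihood via `glm`, Wald standard errors — matching how
published odds ratios with symmetric log-scale CIs are produced) and
applies the two standard inclusion filters *strictly*: imputation quality
> 0.5 and minor allele frequency > 1%, with the MAF computed in the
analysis sample. Excluded variants are logged with their reason; failed
per-variant fits (e.g. separation) yield `NA` records rather than
aborting a scan.

`genomic_lambda()` computes $\lambda = \mathrm{median}(\chi^2)/0.4549$,
and `apply_genomic_control()` divides the $\chi^2$ statistics by
$\max(\lambda, 1)$, inflates SEs by $\sqrt{\max(\lambda, 1)}$ and
recomputes p-values; $\lambda < 1$ is never used to deflate (the usual
convention — the statistic is a one-sided correction for inflation). A
flag on the record set makes double application an error, since the
correction is not idempotent. The case-only quantitative scan is
GC-adjusted under the same rule by the pipeline; whether the original
analyses did so is not documented, so the adjustment is flagged in the
output where it can be disabled.

## Meta-analysis

`fixed_effect_meta()` pools study estimates with inverse-variance weights
$w_i = 1/\mathrm{se}_i^2$; Cochran's $Q$ quantifies heterogeneity and a
`directions` string records per-study signs. `random_effects_meta()` is
the DerSimonian–Laird moment estimator: transparent, standard, and used
here as a sensitivity analysis (the published analysis cited a different
random-effects formulation without giving formulas; DL is this package's
documented choice). `se_from_ci()` recovers $(\beta, \mathrm{se})$ from
printed ORs and 95% CIs using the exact 97.5% normal quantile 1.959964,
with a 2% tolerance for rounding in printed tables.

Two policy details are deliberate:

* the SNP-presence rule ("present in at least half of the studies") is
  evaluated as `2 * count >= k_total` in integers, so odd study counts
  cannot produce floating-point ties;
* significance tiers use strict inequalities — genome-wide at
  $p < 2.5\times10^{-8}$ (half the conventional $5\times10^{-8}$, because
  two stratified scans are run), suggestive at $p < 5\times10^{-7}$.

Allele harmonization before pooling flips $\beta$, $z$ and EAF when a
study's effect allele is the reference's other allele, and drops variants
whose allele pairs do not match at all.

## Known-locus enrichment and risk scores

`sign_enrichment_test()` counts loci whose lean OR exceeds their obese OR
and computes the exact binomial tail against 0.5. The one-sided tail in
the pre-specified direction (lean larger) is the headline number, the
two-sided value is always reported alongside, and ties at full input
precision are excluded with the count reduced. The package ships the
36-locus published table (`known_t2d_loci()`) on which 29 of 36 loci are
lean-larger.

`weighted_allele_score()` computes $S_i = \sum_j w_j g_{ij}$ with
published per-allele log-ORs as weights, imputing missing dosages by
$2\times$EAF and flipping $g \to 2 - g$ where the genotype counts the
other allele. `fit_score_model()` regresses case status on
$S_i / \bar{w}$, so the reported OR is per *average-weighted risk
allele* — a scaling convention (the original analyses did not state
theirs) that makes the fit invariant to rescaling all weights.
`quintile_ors()` ranks the pooled sample, forms five bins whose sizes
differ by at most one (ties broken by stable input order), and reports
each bin's Woolf-CI odds ratio against the middle bin; empty cells are
flagged rather than continuity-corrected.

## The pipeline and its demonstration configuration

`run_pipeline()` chains the stages: simulate studies → two stratified
scans per study → genomic control → per-stratum meta-analysis with the
presence rule → tiers → per-variant heterogeneity tests → meta-analysed
case-only scan → sign test over the known loci → risk-score analyses.
All outputs are plain TSV/JSON plus a YAML run log (resolved
configuration, seed, versions), and a given seed reproduces every output
byte-identically.

The shipped demonstration (`inst/extdata/demo_config.yaml`) simulates two
studies totalling 2,000 lean cases, 4,000 obese cases and 20,000 shared
controls over a 50-variant panel: 10 known risk loci ($\beta = \ln 1.2$,
$\delta = -0.05$, giving lean ORs near 1.25 and obese ORs near 1.12 — the
magnitude pattern of the published known-locus table), 3 low-info and 2
rare variants that exercise the QC filters, and 35 null variants that
keep genomic control honest. One modelling subtlety matters in
multi-locus panels: the interaction terms accumulate across loci into an
effective BMI main effect of $\sum_j \delta_j \bar g_j$ per SD, and a
panel of lean-enriched loci would otherwise invert the BMI–disease
gradient and empty the obese-case pool. The demonstration (and the
36-locus simulations in the test suite) therefore choose `bmi_gamma` so
that the *net* gradient is the conventional +0.3 per SD. The
demonstration runs in about a minute on one CPU; the simulation-based
test suite uses 2,000 cases per stratum and 100 replicates where
replicate-level guarantees are asserted.

## What the simulations do and do not show

The generator reproduces the features the analyses rely on: HWE
genotypes, BMI-dependent effect sizes, case ascertainment by BMI with a
shared control pool, imputation noise, and multiplicative disease risk.
It deliberately omits linkage disequilibrium (loci are independent, as
the 36-locus analyses assume), population structure and relatedness
(genomic control is tested on truly null statistics instead), skewed BMI,
and genome-scale variant counts. Passing tests therefore validate the
*statistical machinery*, not robustness to confounding or LD — on real
data those must be handled upstream, as in any GWAS.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS to tolerance $10^{-12}$, max 50 iterations;
  separation or SE > 100 is treated as a per-variant fit failure.
* Bisection for $\alpha$: 60 steps on $[-40, 40]$, prevalence tolerance
  0.2 pp; guaranteed monotone, errors if unmet.
* p-values are computed from the standard normal (or the equivalent 1-df
  chi-square after genomic control); `p = 0` is rejected on file input.
* Quintile ties: stable radix order, so equal scores are assigned bins by
  input position; bin sizes always balanced to within one.
* Summary-statistics files round-trip at full double precision (17
  significant digits; p-values in scientific notation).

## Known limitations

* The DerSimonian–Laird estimator understates uncertainty in $\tau^2$
  for small study counts; it is provided as a sensitivity check, not the
  primary model.
* The naive stratum heterogeneity test is conservative under shared
  controls (see above); its printed-table reproduction is exact, but for
  design work use the case-only machinery.
* The info-score noise model truncates at the dosage bounds, slightly
  biasing EAF estimates for very low-quality variants.
* X-chromosome analysis, covariate-adjusted models, LD-aware conditional
  analysis and mixed-model relatedness corrections are out of scope.
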