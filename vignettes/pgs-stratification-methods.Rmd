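---
title: "Methods: polygenic score construction and lifestyle-stratified obesity risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic score construction and lifestyle-stratified obesity risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`pgstrat` implements a complete polygenic-score (PGS) workflow for a
dichotomized anthropometric outcome — obesity, defined as BMI ≥ 25 kg/m²
(the Japanese clinical definition; the threshold is a configuration
parameter). The workflow has three scientific layers:

1. **Model construction.** Candidate PGS weight sets are built from GWAS
   summary statistics by two families of methods: LD clumping plus p-value
   thresholding (P+T) over a 6 × 4 grid of p-value thresholds
   (1, 5×10⁻¹, 5×10⁻², 5×10⁻⁴, 5×10⁻⁶, 5×10⁻⁸) and r² thresholds
   (0.2, 0.4, 0.6, 0.8), and point-normal Bayesian shrinkage with Gibbs
   sampling over LD windows (LDpred-style) over a seven-value grid of the
   causal fraction ρ (1, 0.3, 0.1, 0.03, 0.01, 0.003, 0.001). The candidate
   with the highest covariate-adjusted AUC on a training cohort is selected.
2. **Risk stratification.** Individuals in validation cohorts are scored,
   normalized, binned into score percentiles, and grouped into low
   (percentiles 1–10), intermediate (11–90) and high (91–100) genetic risk.
   Obesity odds ratios are estimated per category, and lifestyle exposures
   (leisure-time exercise, daily-life activity, estimated sodium intake)
   are analysed as within-cohort quintiles with per-quintile and trend odds
   ratios inside each genetic risk stratum.
3. **Pooling and design evaluation.** Per-cohort log-ORs are pooled by
   fixed-effect inverse-variance meta-analysis, falling back to a
   DerSimonian–Laird random-effects model when the heterogeneity test is
   significant (p < 0.05). A simulation-based power module maps power over a
   grid of heterogeneity (I² ∈ {0, 0.2, 0.4, 0.6, 0.8}) and effect size
   (OR 1.01–1.08 by 0.01) for a three-cohort design.

Because the cohort data this kind of analysis is usually run on are access
restricted, the package ships a synthetic multi-cohort generator that
reproduces the statistical structure the analysis assumes; the entire
pipeline is exercised, tested and benchmarked on generated data.

## The synthetic data generator

### Genotypes

Dosages are generated by thresholding a latent Gaussian: within each LD
block the latent variable follows an AR(1) process with parameter
`block_r`, and `dosage = qbinom(pnorm(z), 2, maf)` maps it through the
Binomial(2, MAF) quantile function. This gives

* exact Hardy–Weinberg marginal genotype frequencies at the target MAF
  (important: the QC module's exact HWE test must not reject clean data),
* exact control of MAF (drawn uniformly from `maf_range`, default
  0.05–0.5), and
* block-diagonal LD that matches the windowed-LD working assumption of the
  shrinkage estimator.

The latent AR(1) parameter is *not* the dosage-scale correlation;
discretization attenuates it (e.g. latent r = 0.9 gives dosage r² ≈ 0.6 at
common MAF). Tests that need a specific dosage-scale LD level verify it
empirically. A latent-Gaussian simulator was preferred over a
haplotype/coalescent simulator because it gives direct, testable control of
the two quantities the methods actually consume — MAF and windowed LD — at
desk scale.

Variant metadata (ids, positions, alleles, MAFs, imputation R²) is derived
deterministically from the configuration seed, so all cohorts simulated
from one configuration share a variant universe, exactly as cohorts imputed
against a common reference panel would.

### Genetic architecture and phenotype

Effects follow the point-normal model: each variant is causal with
probability `rho_causal` (default 0.03) and causal effects are
N(0, h²/(M·ρ)) on the standardized-genotype scale, so total genetic
variance is `h2` (default 0.3, consistent with whole-genome heritability
estimates for BMI of about 0.28–0.30). BMI is

    BMI = bmi_mean + bmi_sd × (G + covariate terms + ε)

with G the standardized genetic value, age/sex terms, lifestyle terms and
Gaussian noise scaled so the liability has unit variance. Defaults
`bmi_mean = 23.2`, `bmi_sd = 3.6` match community-cohort marginals
(mean ≈ 22.8–23.6, SD ≈ 3.5–3.6) and give an obesity prevalence of ≈ 0.31,
inside the 0.20–0.35 calibration band asserted by the tests.

Lifestyle covariates are drawn from gamma distributions matched to cohort
marginals (LTE ≈ 2.6 ± 4.0 MET-h/d, DLA ≈ 22.6 ± 14.1 MET-h/d, sodium
≈ 4.0 ± 0.9 g/d) and enter the liability with slopes per covariate SD:
LTE −0.12 (protective), DLA 0, sodium +0.12. The signs mirror the
directions the stratified analysis is designed to detect; the magnitudes
were chosen once so that trend ORs are detectable at the default cohort
sizes without being caricatures. By default lifestyle is generated
independent of genotype (no gene–environment correlation), matching the
parallel-OR structure the stratified analysis reports; a `gxe` switch adds
a G×LTE interaction for robustness experiments. Between-cohort
heterogeneity of the covariate slopes is controlled by `heterogeneity_tau`
(default 0).

### What the generator does not emulate

Real haplotype structure and long-range LD, population stratification
(hence no principal components — PC adjustment is supported as optional
extra covariate columns in `adjusted_spearman()`), sex chromosomes,
genotyping batch effects, and ascertainment differences between cohorts.
Passing tests therefore demonstrate the *mechanics and calibration* of the
pipeline, not its behaviour under confounding; on real data the AUCs and
ORs will be smaller than on this clean synthetic signal.

## Quality control

Samples are removed for call rate < 0.95, ancestry flags, then sex-mismatch
flags; variants for call rate < 0.95, exact Hardy–Weinberg p < 10⁻⁶, MAF
< 0.01, then imputation R² < 0.3 — in that order, each record counted under
the first filter it fails, so reports are reproducible. All comparisons are
strict, so boundary values survive. The HWE exact test is the two-sided
conditional test with the probability-ordering convention, evaluated by the
standard recurrence over heterozygote counts in log space; it is verified
against a full-enumeration oracle to 10⁻¹² for totals ≤ 200. Dosages are
hard-called (rounded) for the HWE test, since a dosage-aware HWE variant is
not part of the standard QC stack; this is configurable by pre-rounding.

## PGS construction

**P+T** is implemented as p-value-ordered greedy *clumping* (select the
best remaining variant passing the p threshold, discard unselected
neighbours with r² above the threshold), the conventional reading of
"pruning + thresholding" in PGS work; blind window pruning would discard
the index variant itself. Ties in p are broken by (chromosome, position),
making the selected set independent of input row order. Grid points where
no variant passes the p threshold are kept as explicit failure records.

**Shrinkage weights.** The infinitesimal closed form per LD window is
`w = (R + (M/(n·h²)) I)⁻¹ β̂`; with identity LD this reduces to elementwise
shrinkage `n·h²/(n·h² + M)`, an identity used as an exact test. The general
point-normal posterior is sampled by a per-window Gibbs sampler (Rcpp): for
each variant the marginal effect is residualized against the current
sampled effects through the window LD matrix, the posterior inclusion
probability follows from the two-component Bayes factor, and the effect is
drawn from its conjugate posterior. The reported weight is the posterior
mean over post-burn-in sweeps.

Numerical and design choices:

* **LD windows**: fixed-size, non-overlapping, 200 variants by default, in
  (chromosome, position) order. Window size is configuration; anything
  comfortably larger than the simulated LD blocks (100 variants) behaves
  equivalently.
* **Heritability input**: the shrinkage methods require an h² value; it is
  a configuration input (the tests supply the generator's true h², a
  practitioner would supply an external estimate such as LD-score
  regression output).
* **Gibbs schedule**: 100 burn-in + 500 sampling sweeps by default. At
  ρ = 1 the sampler agrees with the infinitesimal closed form within
  Monte-Carlo error (tested); a divergence guard aborts if the mean
  absolute weight exceeds 10× the mean absolute marginal effect, which
  catches the known instability of residualization-based samplers under
  strong LD with small reference panels.
* **Allele orientation**: weights are always stored on the stated effect
  allele; flipped-allele reconciliation (dosage → 2 − dosage) happens at
  scoring time, and unresolvable allele pairs are skipped and counted.

## Scoring and evaluation

Raw scores are dosage-weighted sums over matched variants; missing dosages
are mean-imputed per variant (the common scoring-tool default; a strict
mode errors instead). Normalization is per cohort by default — each
validation dataset is standardized by its own mean and n−1 SD — with a
pooled mode provided as a sensitivity analysis; when cohorts come from a
shared generative model, per-cohort z-scores are exchangeable across
cohorts (the package asserts Kruskal–Wallis non-significance in ≥ 90% of
null replicates).

"AUC adjusted for age and sex" is interpreted as the AUC of the fitted
linear predictor of the logistic model `outcome ~ score + age + sex`
(the joint convention used by standard ROC workflows); the alternative
convention — ROC of the covariate-residualized score — is available behind
`adjustment = "residual"`. Confidence intervals use the DeLong method. The
AUC of the joint predictor equals the Mann–Whitney statistic of the linear
predictor, an identity the tests exploit.

Quantitative-trait association uses a rank-based inverse-normal transform
with the Blom offset 3/8 (the offset is not identified by rank-based
inference; Blom is the common default), least-squares residualization on
age, age², sex and optional extra covariates, then Spearman correlation
with the t-approximation p-value.

Model selection maximizes adjusted AUC; ties break toward fewer variants,
then lexicographic model id.

## Risk stratification

Percentile bins use `ceil(100·rank/n)` with stable tie-breaking — a
deterministic, testable convention under which n = 100 tie-free scores give
exactly one sample per bin and a 10/80/10 low/intermediate/high split.
Prevalence-elevation curves subtract the 1st-percentile prevalence, so the
curve starts at exactly zero and cohorts with different baseline
prevalences are comparable; empty bins are recorded as missing, never zero.

Quintiles of lifestyle exposures are computed *within cohort* (cohorts can
have genuinely different exposure distributions, so cut-offs must be
cohort-specific) with the same rank convention. Trend ORs enter the
quintile as a single numeric 1–5 term in the logistic model — the standard
"p for trend" coding; quintile midpoints would only rescale the
coefficient. All CIs are Wald (`exp(logOR ± 1.96·SE)`).

Sodium intake can be estimated from spot urine with a configurable
power-law formula (`tanaka_coefficients()` holds the published default
coefficients); the estimate is monotone in spot sodium concentration.

## Meta-analysis and power

Fixed-effect pooling uses inverse-variance weights; heterogeneity is
summarized by Cochran's Q, its χ² p-value and I² = max(0, (Q − df)/Q).
The random-effects fallback uses DerSimonian–Laird τ² (the classical
default of the standard meta-analysis packages; REML is deliberately not
implemented) and triggers strictly at p_het < 0.05. Inference on the pooled
log-OR is two-sided normal without Hartung–Knapp correction, matching the
symmetric CIs this workflow conventionally reports.

The power simulation converts I² to τ² via `τ² = I²·v̄/(1 − I²)` with `v̄`
the mean within-study variance, and approximates within-study variance by
the balanced 2×2 formula `var(logOR) ≈ (4/n)(1/p + 1/(1 − p))` (two equal
exposure groups at outcome prevalence p). Each simulated meta-analysis
draws true study effects N(logOR, τ²) and observed effects N(true, vᵢ) and
runs the same fixed/random fallback logic as the analysis itself, so the
reported power reflects the procedure actually used, including the slight
size inflation the fallback can introduce. At OR = 1 the size is within
Monte-Carlo error of α (tested), and at I² = 0 the power matches the
closed-form fixed-effect formula.

## Pipeline, determinism and problem sizes

`run_all()` executes the stages in flowchart order from one validated
configuration (YAML or list; unknown keys are rejected, defaults are
filled) and writes tidy TSVs plus a checksum manifest; re-running an
identical configuration reproduces identical checksums. Per-stage seeds
are derived as `seed + 97 × stage_index`, so any stage can be re-run in
isolation.

The default study scale — 2,000 variants in 20 LD blocks, a 20,000-sample
discovery GWAS, a 3,000-sample training cohort and three validation
cohorts of 2,000 — was chosen as the smallest design at which model
selection is stable and stratified trend tests are informative; the test
suite uses this scale for the end-to-end recovery checks and much smaller
panels for unit-level oracles. On this clean synthetic signal the selected
model reaches a validation AUC around 0.75; real-data AUCs for BMI-based
obesity are typically far lower because real GWAS signal is spread over
hundreds of thousands of variants and cohorts carry confounding this
generator does not emulate.

## Known limitations

* Windowed LD ignores cross-window and cross-chromosome correlation.
* The Gibbs sampler assumes the summary statistics and LD reference come
  from comparable populations; mismatch is not modelled.
* The power module's within-study variance model is a balanced-design
  approximation; designs with rare exposures need a bespoke variance.
* Percentile and quintile conventions are exact but not unique; other
  rank conventions shift bin membership for tied scores.
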