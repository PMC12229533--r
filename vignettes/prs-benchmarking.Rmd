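---
title: "Benchmarking polygenic risk scores across diverse ancestries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking polygenic risk scores across diverse ancestries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsbench)
```

## The problem

A polygenic risk score (PRS) summarizes a person's genetic liability to a
disease as a weighted sum of risk-allele dosages, with weights taken from
genome-wide association study (GWAS) effect sizes (the *base data*). Most
base data come from European-ancestry studies, and scores built from them
transfer poorly to other populations because allele frequencies, linkage
disequilibrium (LD) and statistical power all differ across ancestries.
`prsbench` implements the machinery needed to quantify that transfer gap on
case-control cohorts: two PRS construction strategies, a common evaluation
suite, and a synthetic multi-ancestry cohort generator with known ground
truth so every step can be validated end to end.

The two strategies are:

* **Fixed-panel PRS** (`score_fixed_panel()`): a predefined panel of risk
  variants — typically the 90 genome-wide-significant Parkinson's disease
  risk variants from the largest European meta-analysis — is scored with
  effect sizes from any harmonized, ancestry-specific base data. The *valid
  predictors* are the panel variants present in both base and target after
  harmonization; with diverged cohorts this is routinely fewer than the
  panel size, which is itself part of the transfer story.
* **Clumping + thresholding PRS** (`fit_ct()`): from genome-wide (typically
  multi-ancestry) summary statistics, greedy LD clumping keeps the most
  significant variant per LD neighborhood (default 250 kb window,
  r² < 0.1, LD estimated from the target cohort itself), and a grid of
  p-value thresholds from 5e-8 to 5e-2 (decade steps) is scanned for the
  best-fit model.

## Models and conventions

**Liability threshold model.** Disease status is modelled through a latent
standard-normal liability; an individual is a case when liability exceeds
`qnorm(1 - K)` for prevalence `K`. Package defaults follow the disease this
package was built around: `K = 0.005` and liability-scale heritability
`h2 = 0.22`.

**Standardization.** Raw scores are z-scored over the full scored cohort
(cases and controls together), so logistic coefficients are log odds ratios
per score standard deviation. Standardizing within cases or controls alone
would change the odds ratios; the cohort-wide convention matches how OR per
SD is usually reported.

**Best-fit selection.** For each threshold the logistic *full* model
(PRS + sex + age + covariates) and *null* model (covariates only) are
fitted; the selection metric is the incremental Nagelkerke pseudo-R²
(full minus null). "Maximal pseudo-R²" is ambiguous between the full and
incremental value; the incremental reading is the one mirrored by
standard clumping-and-thresholding tools, so it is used here, and only
thresholds retaining fewer SNPs than samples are eligible (an overfitting
guard). Ties go to the stricter threshold.

**Liability-scale R².** The incremental observed-scale R² is converted to
the liability scale with the Lee et al. (2012) case-control
transformation (`liability_r2()`), using a configurable prevalence
(default 0.005). At `P = K` the transformation collapses to
`r2 K (1 - K) / z²`, which the tests check to 1e-12.

**Covariate sets.** Association models adjust for sex, age, and either
principal components (`PC1..n`, recomputed per cohort by
`compute_pcs()`) or ancestral admixture proportions (`ADM*` columns, one
simplex component dropped to avoid collinearity with the intercept).

**Evaluation.** `roc_auc()` computes the concordance AUC with DeLong
structural-component variances; `delong_compare()` tests two correlated
AUCs on the same samples; `operating_point()` picks the ROC point closest
to (0, 1) (ties toward higher sensitivity) and reports accuracy with an
exact Clopper-Pearson interval, balanced accuracy, sensitivity and
specificity. Metrics are computed on the fitted probabilities of the
covariate-adjusted model by default (`use_fitted = FALSE` gives the raw
PRS ROC); whether published per-cohort AUC tables use the adjusted or raw
score is usually unstated, so both are exposed.

## The synthetic-data generator

Real multi-ancestry consortium data are access-restricted, so the package
ships a generator (`sim_config()`, `simulate_cohort()`,
`simulate_base_gwas()`) that emulates the statistical structure the
analysis depends on, with full ground truth:

* **Ancestry divergence**: per-ancestry allele frequencies follow the
  Balding-Nichols model around ancestral frequencies drawn
  Uniform(0.05, 0.95), with divergence parameter `fst` (default 0.1, a
  typical between-continental-population value).
* **LD**: haplotypes are generated per block (default 10 variants) by
  thresholding a latent AR(1) Gaussian (default correlation 0.7) at the
  per-variant frequency quantile; blocks are independent. The implied
  pairwise allele correlation is checkable against a latent-Gaussian
  oracle, which the tests do. No recombination map is emulated; LD decay
  within blocks is geometric by construction.
* **Architecture**: causal variants (default 90, placed at most one per
  block so their standardized effects are linkage-independent and sum
  exactly to `h2_liability`) receive shared standardized effects across
  ancestries; frequencies, and hence per-allele effects and LD, diverge.
  This mirrors the view that cross-ancestry transfer degrades mainly
  through frequency and LD divergence, without asserting effect-size
  heterogeneity (ancestry-specific effects can be emulated by supplying
  `causal_beta` per run).
* **Ascertainment**: case-control cohorts are accumulated by rejection
  sampling, which is exact; at prevalence 0.005 this costs roughly
  `n_cases / 0.005` population draws, so the sampler is implemented in
  compiled code and a budget (`max_attempts`) guards runaway requests.
  Demographics are drawn to resemble the motivating cohorts (cases
  58.9 ± 11.8 years at onset; controls 62.4 ± 13.0 at collection; sex
  Bernoulli(0.5)).
* **Admixture**: optional per-sample Dirichlet admixture proportions;
  each haplotype block independently originates from one ancestry drawn
  with those proportions.
* **Determinism**: all randomness flows from `cfg$seed` through fixed
  per-operation sub-streams, so cohorts and their matching base GWAS
  share one ground truth and every artifact is bit-reproducible.

What the generator does *not* emulate: genotyping error and imputation
uncertainty, non-random missingness, relatedness, sex chromosomes,
realistic recombination maps, and ancestry-specific causal effects (by
default). Passing tests on synthetic cohorts therefore validate the
statistical machinery, not robustness to those real-data artifacts.

## Power module

`prs_association_power()` follows the Dudbridge (2013) two-stage design
for a binary trait: per-marker log odds ratios estimated in a
case-control training sample (sampling variance `1/(n P (1-P))` per
standardized dosage), a weighted score tested for association in an
independent target sample of the same size. The expected score-liability
correlation combines the markers' liability variance `h2` with the
estimation noise `m / (n P (1-P) Δ²)`, where `Δ = z / (K (1-K))` is the
case-control difference in mean liability; the observed-scale R² in the
ascertained target uses truncated-normal case/control liability means and
variances, and the association test is non-central chi-square with
`λ = n R² / (1 - R²)`. With `h2 = 0` the power equals `α` exactly.
`min_sample_size()` bisects for the smallest n meeting the target power
and verifies the bracket monotonically.

Two conventions deserve mention. First, the `h2` argument is the
liability variance explained *by the score's markers*; the headline
configuration plugs in the trait's full heritability (0.22 for 90
markers), a widespread convention that overstates what a 90-variant score
actually explains — it is reproduced here deliberately, with this caveat.
Second, `null_fraction` scales the effective explained variance to
`h2 (1 - null_fraction)`: without a marker-selection step a null fraction
can only matter through the variance it removes, and this keeps power
monotonically decreasing in the null fraction. The suite validates the
formulas against genotype-level simulation of the full two-stage design
(weights estimated by per-marker logistic fits in a simulated training
cohort, tested in an independent simulated target), at a prevalence where
rejection sampling is cheap.

## Numerical choices and degenerate inputs

* Missing dosages are mean-imputed per variant for scoring, LD and PCs
  (the QC call-rate filter bounds how much imputation can happen).
* HWE uses the exact conditional test on genotype counts, controls only,
  with dosages rounded to the nearest genotype.
* PCs: columns centered at twice the counted-allele frequency, scaled by
  `sqrt(2 f (1-f))`; constant columns are dropped with a warning; each
  component's sign is fixed by its largest-magnitude loading.
* Clumping ties (equal p) break by position then variant key, making the
  index set deterministic; the suite checks equality with a brute-force
  reference on a thousand random instances.
* A PRS with zero variance (no polymorphic valid predictor) raises a
  degenerate-score error rather than returning NaNs; logistic
  non-convergence marks the grid row and excludes it from best-fit
  selection; quasi-separation in the association fit is reported as an
  error suggesting a penalized refit.
* Palindromic (A/T, C/G) variants are dropped in harmonization by
  default; the optional frequency rescue keeps them only when both
  sources report frequencies on the same side of 0.5 and at least 0.1
  away from it. Indels are matched on exact allele strings and never
  strand-flipped.

## Problem sizes

The shipped tests and the acceptance checks run on deliberately modest
problem sizes chosen to exercise every code path at comfortable desk
scale: cohorts of a few hundred to 4,000 samples, 90-300 variants, 100-500
replicates for calibration checks, 20,000-50,000 population draws for
distributional checks. These sizes give the quoted tolerances (binomial
3-SE bands, ±0.02 on AUC oracles, ±10% on heritability recovery)
comfortable margins while keeping a full run in minutes.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_ancestries = 2, fst = 0.1, n_variants = 300,
                  n_causal = 30, h2_liability = 0.22, prevalence = 0.005,
                  n_cases = 1000, n_controls = 1000, seed = 1)
target <- simulate_cohort(cfg, ancestry = 1)
cohort <- compute_pcs(target$cohort, 10)
base <- simulate_base_gwas(cfg, n_train = 4000, ancestry = 2)
harm <- harmonize_sumstats(base, cohort$variants)

tv <- cohort$variants[target$truth$variants$causal, ]
panel <- variant_key(tv$chrom, tv$pos, tv$counted_allele, tv$other_allele)
prs <- score_fixed_panel(cohort, harm$sumstats, panel)
evaluate_prs(cohort, prs, "pcs")

ct <- fit_ct(cohort, harm$sumstats, prevalence = 0.005)
delong_compare(evaluate_prs(cohort, prs, "pcs")$scores,
               evaluate_prs(cohort, ct$prs, "pcs")$scores,
               cohort$samples$phenotype)
```

The `analysis/` directory of the source repository runs this workflow at
larger scale as a numbered sequence of scripts (simulate, fixed-panel
scoring, C+T fitting, model comparison, power), writing plot-ready tables
under `results/`.

## Known limitations

* LD clumping uses the target cohort as its own LD reference; no external
  reference panel option is provided (none is needed for the analyses the
  package reproduces).
* No LD-aware re-weighting (lassosum/PRS-CS-style) of either model; the
  fixed panel takes weights as given and C+T is deliberately the standard
  greedy procedure.
* The liability-scale conversion assumes a single, externally supplied
  prevalence; prevalence misspecification propagates multiplicatively
  into the adjusted R².
* Genome-build liftover, kinship handling, X-chromosome dosage
  conventions and imputation against external panels are out of scope;
  inputs are assumed unrelated, autosomal and on one build.
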