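---
title: "Dissecting expression into genetically and environmentally regulated components"
author: "exprDissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting expression into genetically and environmentally regulated components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprDissect)
```

## The model

Bulk expression of a gene in an individual is treated as the sum of three
parts:

* **GReX** — the *genetically regulated* component, the part predictable
  from common cis variants (within ±1 Mb of the gene boundaries,
  inclusive at both ends). It is imputed as a sparse linear score
  `GReX[s, g] = Σ_v w(g, v) · dosage(s, v)` over effect-allele-aligned
  ALT dosages, with per-gene weight vectors of the kind produced by
  elastic-net TWAS training on a reference panel.
* **EReX** — the *environmentally regulated* component, defined
  operationally as the residual of a per-gene ordinary least squares
  regression (with intercept, no covariates) of observed expression on
  imputed GReX. It absorbs environmental variance together with
  anything the cis model does not capture (trans effects, rare
  variants), which is a documented interpretation limit, not a flaw of
  the estimator.
* noise.

Both components, and the observed expression itself, are tested for
association with a binary case/control phenotype by a likelihood-ratio
test on nested logistic models: the null model regresses status on a set
of confounders, the full model adds the single gene variable, and
`LRT = 2(ℓ_full − ℓ_null)`, floored at zero.

### Covariate policy

Expression principal components are confounders for the observed and
EReX analyses but **not** for GReX — GReX is a deterministic function of
genotype, so adjusting it for expression-derived axes would reintroduce
the very signal being isolated. Genotype principal components
(population stratification) enter every analysis. This asymmetric
policy is enforced by `covariatePolicy()` and violating it is an error,
not a warning.

### Permutation calibration

P-values come from a Freedman–Lane permutation scheme: the gene variable
is regressed on the null-model covariates, the residuals are permuted
with a dedicated seeded generator, the fitted values are added back and
the LRT recomputed. With no covariates this reduces exactly to permuting
the gene variable. The default run uses 8000 initial permutations; genes
with no exceedance escalate to 1,000,000 total permutations, and a count
still at zero is reported as the upper bound `1/B` with a flag so the
downstream ranking stays total. The smallest p-value the initial stage
can produce is therefore `1/8000 = 1.25e-4`. Permutation streams are
derived per (gene, component) from the run seed by position, so results
are independent of execution order and of R's global RNG state; the
shuffles themselves use a private `mt19937_64` Fisher–Yates in compiled
code and are identical across platforms.

Perfect separation of the logistic fit (rare at cohort scale but
possible inside a permutation loop) is detected from the fitted
probabilities and handled by refitting with a small ridge penalty
(1e-6) on the gene coefficient, flagged in the output. Convergence of
each fit uses a relative log-likelihood tolerance of 1e-10 with at most
100 Newton iterations.

## Variant QC and heritability

Variants are kept when MAF > 0.05 **strictly** and the exact
Hardy–Weinberg test p-value exceeds 0.05 strictly; a variant at MAF
exactly 0.05 is removed. The HWE test is the standard exact conditional
test (no mid-p): conditioning on the minor-allele count, each
compatible heterozygote count is weighted by its conditional
probability and the p-value sums the probabilities of configurations no
more probable than the observed one. The test suite checks it against
brute-force enumeration for every genotype configuration up to n = 50.

Local heritability is estimated by single-variance-component REML:
the genomic relationship matrix is `Z Zᵀ / m` from column-standardized
cis dosages, and the restricted likelihood of
`y ~ N(μ, σ²_g K + σ²_e I)` is maximized over the ratio
`h² = σ²_g / (σ²_g + σ²_e)` by bounded one-dimensional search
(tolerance 1e-6) on the eigenbasis of K, with the rank-deficient
remainder of the spectrum handled in closed form; estimates are clamped
to [0, 1]. A one-parameter profile is deterministic and cannot fail to
converge, which is why this parameterization was chosen over iterative
multivariate REML. `remlProfile()` exposes the profile so tests can
verify the optimizer against a 101-point grid.

Weight training (`trainWeights`) uses the elastic net with mixing
parameter 0.5 (the convention of published TWAS weight sets) and an
internally cross-validated penalty; the reported `cv_r2` is the squared
Pearson correlation between ten-fold out-of-fold predictions and
observed expression, hence non-negative. All fold assignments derive
from the run seed. Across genes `cv_r2` is expected to track the REML
h² from below — shrinkage keeps prediction R² under the heritability
ceiling — and the package checks that their correlation is strongly
positive on simulated reference cohorts.

## What the synthetic cohorts emulate

`simulateCohort()` builds a cohort in which every downstream quantity
has a known ground truth. Defaults are the desk-scale study conditions
used throughout the tests: 922 subjects split 463 cases / 459 controls,
200 genes with 30 independent cis SNPs each (8 causal), ALT frequencies
uniform on [0.05, 0.5] with HWE-binomial genotypes, and cis
heritability 0.15 per gene — the middle of the twin-study range for
blood expression (roughly 0.10–0.26). Per gene the genetic score is
rescaled to an empirical SD of `sqrt(h²)`, the environmental component
is Normal with 70% of the non-genetic variance (`envShare = 0.7`, a
choice balancing structured environment against iid noise; results are
insensitive to it because the association stage sees only their sum),
and the remainder is noise, so
`observed = trueGrex + trueEnv + noise` holds exactly by construction.

Case/control labels are drawn liability-style: a logistic deviate is
added to the (optionally) genetically driven liability and the top
`nCases` subjects become cases, which achieves exact case/control
counts — the natural emulation of a fixed-size case/control design.
Environmental case/control effects are then added as a mean shift of
`envEffectSize` environmental SDs in cases for the selected genes.
Draw order (genotypes, weights, environment, noise, covariates,
liability) is fixed, so a config plus seed fully determines the cohort.

What the generator deliberately does **not** emulate: linkage
disequilibrium (variants are independent), trans-eQTL architecture,
non-Gaussian expression noise, and realistic clinical confounder
structure (clinical covariates are iid standard normal). Passing tests
therefore demonstrate correctness of the estimators and calibration of
the permutation machinery under a clean additive architecture, not
robustness to LD or to heavy-tailed counts.

### Expression PCs at desk scale

In the cohort-scale simulations used for power checks, half the genes
carry the case/control shift. With such a dense signal the leading
expression PC is nearly collinear with the phenotype, and conditioning
on it would absorb the association being measured — a small-universe
artifact: with ~5000+ genes and sparse signal, expression PCs capture
batch and global variation instead. The power simulations therefore run
with clinical and genotype-PC covariates only, while the default
pipeline (`nExprPCs = 10`) keeps the full policy for realistic-scale
data. This is a deliberate design decision, recorded here.

## Enrichment and π₁

Ranked top-N over-representation uses the upper-tail hypergeometric
including the observed overlap (no mid-p), with draw sizes
N ∈ {30, 60, 100, 150, 200, 300} by default, over the universe of genes
with all components available. Permutation p-values tie heavily at the
b/B resolution, so the ranking breaks ties by larger LRT statistic and
then gene id — a total order is required for top-N to be well defined.

π₁ estimation assumes p-values above λ = 0.5 are uniform null:
`π₀ = #{p > λ} / ((1 − λ) m)`, `π₁ = 1 − π₀` clamped to [0, 1]. A
single fixed λ (no spline extrapolation) keeps the estimator
deterministic and directly testable; at λ = 0.5 it is slightly
conservative when alternatives have mass above λ, which the mixture
recovery test quantifies.

## Numerical choices and degenerate inputs

* Dosages live in [0, 2]; missing genotypes are imputed to the
  per-variant mean before anything else runs.
* Effect-allele harmonization: a weight whose effect allele equals the
  VCF REF allele has its dosage flipped to `2 − d`; strand-ambiguous
  (A/T, C/G) variants are used as-is with a warning; an effect allele
  matching neither allele drops the variant.
* Zero-variance GReX genes keep centered observed expression as EReX
  and are flagged, not dropped, so EReX analyses cover all expressed
  genes.
* A zero-variance gene variable short-circuits to LRT = 0, permutation
  p = 1.
* GReX summation order is fixed (ascending variant id) so predictions
  are bit-reproducible.
* Text round trips of expression matrices use %.17g formatting, making
  checkpointed stage outputs exactly re-runnable.

## Problem sizes used in the shipped checks

The simulation-based checks run at the cohort size of the emulated
study (n = 922, 463/459) with gene counts chosen per question: 500
genes for null calibration (B = 2000 permutations), 200 genes (100
environment-shifted at 0.5 environmental SDs + 100 null, B = 1000) for
the power contrast, 40 genes at h² = 0.3 for decomposition recovery,
and a 60-gene reference cohort (n = 500) with h² spread over
[0.05, 0.6] for the R²–h² relationship. These sizes give the binomial
or correlation precision each check needs while keeping the whole suite
runnable on a laptop.

## Known limitations

* EReX inherits everything cis prediction misses; it is an upper bound
  on the environmental component.
* The internal REML uses a single GRM; no multi-component or
  relatedness-aware modelling.
* No LD means simulated weight training is easier than on real panels;
  cv_r2 values are optimistic relative to field experience.
* The CLI accepts plain dosage TSV and uncompressed VCF; PredictDB
  SQLite and binary genotype formats are out of scope (a documented
  TSV schema is the interchange).
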