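---
title: "Polygenic scoring with a continuous shrinkage prior: model, choices, limits"
author: "shrinkPRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scoring with a continuous shrinkage prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the defaults and why they are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical decisions a maintainer would otherwise have to reverse-engineer
from the code.

## The problem

Single-variant GWAS effect estimates are marginal: each SNP's coefficient
absorbs the signal of every variant it is correlated with. Summing raw
marginal effects over-counts in regions of strong linkage disequilibrium
(LD) and drowns true signals in noise from the hundreds of thousands of
null SNPs. The continuous-shrinkage approach treats the vector of true
standardized effects as sparse-but-not-exactly-zero and re-estimates it
jointly, conditioning on an LD reference panel, so that polygenic scores
are built from posterior rather than marginal effects.

## Model and sampler

Marginal effects are first put on the standardized-genotype scale. By
default the package uses the p-value route
$\hat\beta_j^{std} = \mathrm{sign}(\hat\beta_j)\, z(p_j)/\sqrt{n}$, with
$z(p)$ the upper $p/2$ normal quantile; a SE-based mode
($(\hat\beta_j/se_j)/\sqrt n$) is available behind a flag. The p-value
route is the default because the typical summary-statistics dialect
carries (BETA or OR) and P, and because it is robust to effect columns
reported on mismatched scales. P-values are floored at $10^{-323}$ before
the quantile transform; the floor is the smallest double for which the
quantile stays finite and it affects only genome-wide-extreme SNPs, whose
standardized effect is then bounded rather than infinite.

Within each LD block with correlation matrix $D$:

$$\hat\beta \mid \beta \sim N(D\beta, (\sigma^2/n)\,D), \qquad
  \beta_j \sim N(0, (\sigma^2/n)\,\phi\,\psi_j),$$

with a Gamma–Gamma global–local mixture on the scales: $\psi_j \sim
\mathrm{Gamma}(a,\delta_j)$, $\delta_j \sim \mathrm{Gamma}(b,\phi)$.
Defaults $a = 1$, $b = 1/2$ give heavy-tailed, horseshoe-like shrinkage:
strong near the origin, weak in the tails. The full conditionals are:

* $\beta_{blk} \sim N(A^{-1}\hat\beta_{blk}, (\sigma^2/n) A^{-1})$ with
  $A = D + \mathrm{diag}(1/\psi)$, drawn through the lower Cholesky factor
  (one triangular solve for the mean, one for the noise);
* $\psi_j \sim \mathrm{GIG}(a - \tfrac12,\; 2\delta_j,\;
  n\beta_j^2/\sigma^2)$, then capped at 1;
* $\delta_j \sim \mathrm{Gamma}(a + b,\ \psi_j + \phi)$;
* auto mode: $w \sim \mathrm{Gamma}(1, \phi + 1)$, then $\phi \sim
  \mathrm{Gamma}(pb + \tfrac12,\ \sum_j\delta_j + w)$;
* $1/\sigma^2 \sim \mathrm{Gamma}\!\big((n+p)/2,\ e\big)$, with
  $e = \max\!\big(\tfrac n2(1 - 2\beta^\top\hat\beta +
  \sum_{blk}\beta^\top A \beta),\ \tfrac n2\sum_j \beta_j^2/\psi_j\big)$;
  the max() guard keeps the rate positive when the quadratic form goes
  slightly negative through LD-reference mismatch.

The fixed scan order is $\beta \to (\psi,\delta) \to \phi \to \sigma^2$.
Any fixed scan is a valid Gibbs sampler with the same stationary
distribution; this order updates the scales immediately after the effects
they govern. Because $\psi$ is updated before $\delta$, the couplers need
an initial value: they start at their conditional mean under $\psi = 1$,
$(a+b)/(1+\phi_0)$. Initial state is $\beta = 0$, $\psi = 1$,
$\sigma^2 = 1$, $\phi_0 = 1$ in auto mode.

The $\psi \le 1$ cap bounds the per-SNP prior variance at the global
level $\phi\sigma^2/n$, which stabilizes the auto-$\phi$ chain: without
it, a handful of runaway local scales can absorb the shrinkage budget and
send $\phi$ into drift.

The GIG sampler is the package's own (C++): a Devroye-type rejection
sampler from a three-piece log-concave envelope of the two-parameter form,
with the Gamma short-circuit at $\chi = 0$ and the $\lambda < 0$ case
handled by inversion. It consumes R's RNG stream, so every chain is
bit-reproducible from `set.seed()`. Its mean and variance are tested
against Bessel-function closed forms and direct quadrature across the
parameter domain.

### Chain configuration

Program defaults are 1,000 iterations, 500 burn-in, thinning 5 — a
proportionally scaled version of the 10,000/5,000/5 `"benchmark"` preset
in `mcmcConfig()`, which matches the run length commonly used for
full-scale, multi-million-SNP analyses. On the simulated architectures
used in the test suite the chain mixes within a few hundred iterations;
the running posterior mean (not stored samples) keeps memory flat, with a
`keepTrace` flag for diagnostics and Monte-Carlo standard errors
(`chainMCSE()`, batch means).

Chromosomes are independent given the prior, so each gets its own RNG
stream derived from the user seed (`seed + 7919·k`); parallel execution
over chromosomes is then exactly identical to sequential execution, which
the tests assert at file level.

### Numerical safeguards

Near-singular LD blocks (long stretches of near-perfect LD, or reference
panels smaller than the block size) can defeat the Cholesky
factorization. On failure the sampler adds jitter
$\varepsilon = 10^{-6}\,\mathrm{tr}(A)/\dim(A)$ to the diagonal, doubling
up to six times before giving up with the block index in the error. A
non-finite draw aborts the chain with its iteration index rather than
silently propagating NaNs into the running mean.

## Input handling

**Summary statistics** are whitespace- or tab-delimited with a header;
columns may be in any order and renamed freely via the column map (role →
name). OR columns are converted to log-OR on input. Duplicated SNP ids
are fatal (the id is the join key everywhere); non-numeric fields are
reported with their line number.

**Harmonization** intersects sumstats, LD reference and target variant
list, and resolves allele orientation per SNP in fixed precedence: direct
match, allele swap (effect sign flips), strand complement,
swap-complement (sign flips). Palindromic variants (A/T, C/G) therefore
resolve through the non-complement configurations and are retained by
default — the behavior that keeps output weights aligned with upstream
tools — with a `dropAmbiguous` flag for the conservative choice. The
output follows reference SNP order and allele orientation, which makes
harmonization idempotent (tested).

**QC filters** mirror standard practice: variants are removed at
MAF ≤ 0.01, Hardy–Weinberg equilibrium $P < 10^{-10}$ (one-df chi-square,
`hwePvalues()`), or |MAF − reference MAF| > 0.10; the report counts
removals per rule.

**LD reference**: correlation matrices are computed per block from
reference genotype dosages. Block boundaries come from a boundary table
when supplied, else fixed windows of 1,000 SNPs (configurable) — published
LD-block maps can be fed in as a boundary table, they are not re-derived.
Storage is one plain-text matrix per block at 17 significant digits plus a
snpinfo/manifest pair, so a save/load round trip is bit-exact and
diff-able; symmetry, unit diagonal, partition and positive
semi-definiteness (eigenvalues ≥ −10⁻⁸) are checked on load. Genotype
input is a dosage matrix (TSV) with PLINK `.bim` variant metadata; the
package does not parse binary `.bed` files.

**Scoring** counts dosages toward each weight's effect allele (the same
four-configuration logic as harmonization, complemented dosages `2 − d`
for swapped coding), imputes missing dosages at twice the scoring-cohort
allele frequency by default (`drop` sets them to zero contribution), and
z-scales scores to mean 0, SD 1 — evaluation downstream uses only the
scaled scores, which makes the raw-sum-vs-average choice immaterial.

## Evaluation metrics

* Quantitative: OLS of phenotype on score + covariates versus covariates
  only. Both the full-model and the incremental R² are always reported;
  the full-model value is the headline by default since
  covariate-inclusive R² is what cohort studies typically tabulate.
  Covariates enter as joint model terms, not pre-residualization.
* Binary: AUC by the rank/Mann–Whitney formulation (ties count ½; equal
  to exhaustive pair counting, which the tests assert on random
  instances); Nagelkerke $R^2_N = (1-(L_0/L_1)^{2/n})/(1-L_0^{2/n})$ from
  covariate-adjusted logistic fits; odds ratio of the top score decile
  against the bottom 90%, boundary ties going to the top stratum, with the
  Haldane–Anscombe 0.5 correction (flagged and warned) on zero cells. AUC
  is covariate-free by default.
* Concordance between two weight sets (replicate chains, or two
  implementations): per-SNP squared error, its median, and a paired
  t-test across SNPs — degenerate zero-variance differences are handled
  explicitly (identical inputs: t = 0, p = 1). Replicate metrics are
  summarized as mean and k−1 SD.

## The synthetic-data generator

The generator exists so that every module — and the pipeline end-to-end —
is testable with known ground truth and no downloads. It emulates:

* **Block LD**: latent Gaussian AR(1) within blocks (default correlation
  0.5, blocks of 250 SNPs), zero between blocks — deliberately matching
  the sampler's block-conditional structure so that recovery failures
  indicate sampler defects, not LD misspecification.
* **Hardy–Weinberg genotypes**: two independent latent haplotypes per
  individual, each dichotomized at the MAF quantile and summed, so HWE
  holds by construction and the HWE filter is testable against true
  positives only. Note that thresholding attenuates the dosage
  correlation below the latent AR(1) value (the tetrachoric relation);
  the LD tests compare against the orthant-probability quadrature oracle,
  not against the latent parameter.
* **Additive polygenic architecture**: a causal fraction (default 5%)
  with standardized effects $N(0, h^2/(\pi p))$; environmental noise is
  scaled to the realized genetic variance so the heritability ratio lands
  on the configured $h^2$ (default 0.5) up to noise-realization error.
* **Liability-threshold binary traits**: case status above the empirical
  $1-K$ liability quantile (default prevalence 0.2).
* **Marginal GWAS**: per-SNP simple linear regression for quantitative
  traits, logistic score tests for binary, emitting the sumstats dialect
  the parser reads.

Default cohort sizes (GWAS 20,000; target 2,000; reference panel 2,000;
2,000 SNPs) describe a study large enough for clear signal at $h^2=0.5$
yet small enough that the full validation pipeline — including two
replicate 2,000-iteration chains and GWAS-size comparisons — runs in
minutes on one CPU; those are the problem sizes the test suite and the
acceptance script use.

What it does **not** emulate — and hence what passing tests do not show
about real data: realistic haplotype/recombination structure and LD decay,
allele-frequency spectra, between-block LD, ancestry structure and
admixture, GWAS/reference/target panel mismatch, imputation error, sample
overlap between GWAS and target, or covariate-confounded phenotypes. The
simulated covariates (age, sex) are independent of the phenotype; they
exercise the adjustment code paths, not confounding.

## Known limitations

* Single-ancestry: one LD reference, no cross-population joint modeling.
* Dense per-block LD storage; block sizes in the low thousands are the
  practical ceiling per block.
* Genotype input is dosage-matrix text plus `.bim`; no binary PLINK
  reader.
* The auto-$\phi$ update learns a single genome-wide shrinkage level; no
  validation-based grid search over fixed $\phi$ is provided.
* The paired t-test in the concordance protocol treats per-SNP
  differences as exchangeable; under strong LD its effective degrees of
  freedom are optimistic, which is why the calibration test checks its
  rejection rate on replicate chains of the actual sampler.
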