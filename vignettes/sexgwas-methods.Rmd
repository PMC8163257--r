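---
title: "Models and methods behind sexgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexgwas)
```

# The scientific question

Sex differences in the prevalence, presentation and course of psychiatric
and behavioral traits are pervasive, yet most GWASs analyze the sexes
jointly. When male-only and female-only summary statistics exist, the
common-variant architecture can be compared between sexes without any
individual-level data. `sexgwas` implements that comparison at four levels:
total SNP-heritability, genome-wide genetic correlation, individual
variants, and genes/gene sets — together with a synthetic data generator so
that every estimator can be exercised against known truth.

# The statistical model

## LD score regression

For a polygenic trait with SNP-heritability $h^2$ spread over $M$ reference
variants, the expected association chi-square of variant $j$ in a GWAS of
$N$ individuals is

$$E[\chi^2_j] = 1 + \frac{N h^2 \ell_j}{M},$$

where $\ell_j = \sum_k r^2_{jk}$ is the LD score of variant $j$. A weighted
regression of $\chi^2_j$ on $N_j \ell_j / M$ with a free intercept gives
$h^2$ as the slope; the intercept absorbs confounding and (for the
cross-trait version) sample overlap, and is 1 under a clean polygenic
model. The cross-trait analogue regresses $z_{1j} z_{2j}$ on
$\sqrt{N_1 N_2}\,\ell_j / M$; its slope is the genetic covariance, and the
genetic correlation is $r_g = \widehat{\rho_g}/\sqrt{\hat h^2_1 \hat
h^2_2}$, never clipped to $[-1, 1]$ (sampling noise legitimately produces
estimates above 1, and clipping would bias the sex-difference tests).

**Regression weights.** The canonical implementation uses a two-step
iteratively reweighted estimator. `sexgwas` uses a deliberate single-pass
approximation: weights $1/\max(\ell_j, 1)$ (over-counting correction) times
$\big(1 + N \hat h^2_0 \ell_j / M\big)^{-2}$ (heteroscedasticity), with
$\hat h^2_0$ from an unweighted pre-fit clamped to $[0, 1]$. For the
cross-trait regression the heteroscedasticity factor is the product of the
two single-trait factors; this choice makes the self-correlation
$r_g(s, s) = 1$ hold to machine precision, a property the test suite pins.
The approximation changes efficiency, not consistency, and the
block-jackknife SE reflects whatever weights were used.

**Block jackknife.** All LDSC-level standard errors come from delete-one
block jackknifing over 200 contiguous genomic blocks of near-equal variant
count (the tooling default for this family of estimators):
$\mathrm{SE}^2 = \frac{B-1}{B}\sum_b (\hat\theta_{(b)} - \bar\theta_{(.)})^2$.
For the sex difference of a between-trait correlation, the *difference*
$r_{gF(b)} - r_{gM(b)}$ is jackknifed on one shared block assignment, which
makes the test robust to sample overlap among the four cohorts: any shared
noise cancels inside each pseudovalue. Blocks are equal in variant count
rather than physical length — equal-count blocks keep the pseudovalue
variance stable when variant density varies along the genome — and never
span a chromosome boundary.

## Liability-scale conversion

Case-control heritability estimated on the observed (0/1) scale is
converted to the liability scale by
$c = K^2(1-K)^2 / \{P(1-P)\,\varphi(t)^2\}$ with $t = \Phi^{-1}(1-K)$,
where $K$ is the population prevalence and $P$ the sample case fraction.
$K$ differs by sex for most psychiatric traits, so the conversion takes
sex-specific prevalences, and the pipeline accepts several prevalence
*sources* per trait (e.g. registry cumulative incidence vs. survey
prevalence) as configuration, producing one liability estimate per source.
At $K = P = 0.5$ the factor is exactly $\pi/2$, a useful analytic anchor.

## The sex-difference z test

For any statistic estimated separately in the sexes,

$$z = \frac{\mathrm{STAT}_F - \mathrm{STAT}_M}
          {\sqrt{\mathrm{SE}_F^2 + \mathrm{SE}_M^2}},$$

with a two-sided normal p. The sign convention is female minus male
everywhere in the package. The test is exact when the two estimates are
independent and normal, and conservative when they are positively
correlated (overlapping controls, shared population structure). Applied
per SNP on a harmonized pair it quantifies genotype-by-sex effect-size
heterogeneity — correlated with Cochran's Q but signed. The only one-tailed
test in the package is $z = (1 - r_g)/\mathrm{SE}$ for the null that the
between-sex correlation is below 1.

## Cross-trait sharing of sex-differentiated effects

If sex-differentiation is a property of a variant rather than of one
trait's biology, per-SNP sex-difference z scores should correlate across
traits. The package computes the Pearson correlation of two traits' z
scores over their variant intersection and assesses it by a genomic
jackknife over 1000 contiguous blocks, because neighboring SNPs are not
independent observations. The jackknife p uses a normal reference by
default (a t reference with $B-1$ degrees of freedom is available but off,
as $B = 1000$ makes the two indistinguishable). All intersected SNPs are
used rather than an LD-pruned subset; the block jackknife is exactly the
device that makes that valid.

## Gene-level aggregation

Per gene, the statistic is the mean of squared sex-difference z scores over
mapped SNPs (mapping window 0 bp, closed intervals, multi-gene mapping
allowed). Under the null the z vector is multivariate normal with the local
LD matrix $R$ as covariance, so $k \cdot \mathrm{stat} = \sum_i \lambda_i
\chi^2_{1,i}$ with $\lambda_i$ the eigenvalues of $R$. The p-value comes
from Satterthwaite moment matching — a scaled chi-square with
$\mathrm{scale} = \sum\lambda^2/\sum\lambda$ and $\mathrm{df} =
(\sum\lambda)^2/\sum\lambda^2$ — rather than a re-implementation of the
exact MAGMA internals; the test suite holds it against a 50,000-draw
simulation oracle to within 0.2 decades of log p for $p \ge 10^{-4}$. The
two boundary cases are exact: a single SNP reduces to the two-sided
chi-square(1) test, and $k$ perfectly correlated SNPs collapse to one
effective test.

The top 0.1% of genes per trait (ties at the cutoff all included) are
pooled across traits and tested for gene-set over-representation with the
upper-tail hypergeometric against the universe of tested genes, with
Benjamini–Hochberg correction across sets. This replaces rank-based
web-tool enrichment with a transparent, exactly specified test on the same
discrete gene list.

# The synthetic-data generator

The generator works at the summary-statistic level: per LD block with
correlation matrix $R$, the z vector is drawn from
$\mathcal{N}(\sqrt{N}\,R\,\beta,\; R)$ where $\beta$ are standardized true
effects. This is the exact finite-sample distribution implied by the
polygenic regression model above, so generator and estimator meet on the
same mathematical object — the cleanest possible test bed for parameter
recovery. True effects are bivariate normal across the sexes with per-sex
variances $h^2/m_c$ ($m_c$ causal variants) and correlation
$r_{g,MF}$; LD is AR(1) within equal-sized blocks
($\mathrm{cor}(j,k)=\rho^{|j-k|}$, $\rho = 0.5$ by default, giving LD
scores up to $\approx 1.67$); effect-allele frequencies are uniform on
$(0.05, 0.95)$ and enter only through the allelic scaling
$\mathrm{SE}_j = 1/\sqrt{2 N p_j (1-p_j)}$; sexes are disjoint cohorts, so
the cross-sex intercept is 0 by construction.

What this deliberately does **not** emulate: realistic human LD (long-range
LD, variable block sizes), MAF-dependent architectures, population
stratification, genotyping or imputation error, and case-control
ascertainment at the genotype level (binary traits carry $K$ and $P$ as
metadata for the liability conversion, but z scores are generated on the
observed scale). Passing tests therefore demonstrate that the estimators
are correct under their own model assumptions, not that those assumptions
hold in any particular real cohort.

# Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `maf_min` | 0.01 | minor-allele-frequency filter; rare variants have unstable LD scores and effect estimates |
| HLA interval | chr6:25–34 Mb, closed | long-range LD region excluded before regression; closed endpoints are the conservative reading of the conventional "25–34M" |
| `n_blocks` (LDSC) | 200 | jackknife blocks for h², r~g~; the tooling default |
| `n_blocks` (z correlation) | 1000 | finer blocks for the SNP-level correlation, where the statistic is cheap and LD is the dominant dependence |
| `window_bp` | 0 | SNP-to-gene mapping window; gene-body-only mapping |
| `fraction` | 0.001 | top-gene selection per trait |
| `alpha` | 0.05 | family-wise level; Bonferroni thresholds are also reported rounded to 4 decimals, as conventionally printed |
| `drop_ambiguous` | TRUE | A/T and C/G variants are strand-unresolvable from alleles alone and are dropped during harmonization |

# Numerical and design choices

* **Odds ratios are log-transformed at read time**, so every downstream
  test operates on betas regardless of trait type.
* **Coordinates are 1-based inclusive** throughout; BED-style inputs can be
  imported with a 0-based toggle.
* **Harmonization** intersects the two sexes' variants (no reference-panel
  subsetting, no imputation of missing z), flips swapped alleles
  ($\beta \to -\beta$, $\mathrm{eaf} \to 1-\mathrm{eaf}$) and drops
  irreconcilable allele pairs; it is idempotent and order-symmetric, and
  per-variant sample size falls back to the cohort total when absent.
* **Zero-variance regressors** (constant LD scores) define a slope of 0
  rather than NaN, so degenerate inputs fail softly.
* **Non-positive heritability** makes $r_g$ undefined; such estimates are
  flagged, not coerced, and the pipeline's gate (estimate > 0 with the 95%
  CI excluding 0 in *both* sexes) removes the trait from all correlation
  and sex-difference testing while still reporting its heritability rows.
* **Delete-one pseudovalues with negative h² products** are dropped from
  the r~g~ jackknife rather than imputed; the SE then reflects the finite
  blocks that are informative.
* **Multiplicity families** are per analysis table: Bonferroni across the
  heritability sex-difference tests (one test per trait; binary traits
  tested on the liability scale, continuous on the observed scale),
  Bonferroni across the r~g~ < 1 tests, and one BH family each for the
  cross-trait z-score correlations and the between-trait r~g~ sex
  differences. Every output row records its rule, family size and
  threshold, machine-readably.
* **Relabelling a variant's effect allele** jointly in both sexes negates
  its per-SNP z (direction is defined relative to the effect allele) while
  leaving p untouched; the suite pins this as sign-antisymmetry plus
  p-invariance.

# Validation scale

The test suite validates parameter recovery at the scale the estimators are
meant for: 20,000 SNPs in 1000 LD blocks, N = 50,000 per sex, 50 replicates
per setting, with generating $h^2 \in \{0.2, 0.3\}$ and $r_{g,MF} \in
\{0.5, 0.8, 1.0\}$ — recovery is asserted within 2 jackknife SEs in at
least 90% of replicates, and the one-tailed $r_g < 1$ test is asserted to
reject a true $r_g = 1$ in fewer than 5% of replicates at the 16-test
Bonferroni threshold. Null calibration of the per-SNP test runs on 100,000
independent simulated SNPs (type-I error within [0.045, 0.055] at
$\alpha = 0.05$, $\lambda_{GC}$ within $1 \pm 0.02$), and the jackknife SE
of the null z-score correlation is compared against Fisher's
$1/\sqrt{n-3}$ over 200 replicates. Unit tests use smaller instances of
the same generator.

# Known limitations

* The single-pass weighting scheme is slightly less efficient than the
  two-step estimator it approximates; SEs remain honest via the jackknife.
* The sex-difference z test is conservative under positive cross-sex dependence
  (shared controls); no attempt is made to estimate and subtract that
  covariance at the per-SNP level.
* Gene statistics require a local LD source; with synthetic data this is
  the generator's own reference, with real data a user-supplied panel —
  mis-specified LD propagates directly into gene p-values.
* No X-chromosome support: the sex-stratified analysis here is
  deliberately autosomal, as X dosage would confound the comparison.
* Genotype-by-sex interaction modelling proper requires individual-level
  data and is out of scope; the per-SNP z test is the summary-level
  analogue, similar to but not identical to an interaction test.
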