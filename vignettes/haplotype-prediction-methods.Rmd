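---
title: "Haplotype-based prediction and local epistasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based prediction and local epistasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgblup)
```

## The models

All prediction models in this package are variance-component mixed models

$$ y = 1\mu + g_1 + \dots + g_T + e, \qquad g_t \sim N(0, \sigma_t^2 K_t),
\qquad e \sim N(0, \sigma_e^2 I), $$

with a fixed intercept and one genomic relationship matrix per genetic
component. Genotypes are coded as allele counts $m_{ij} \in \{0,1,2\}$; an
inbred (doubled-haploid) panel carries only 0 and 2.

* **GBLUP** uses the additive kernel $G_1 = \tfrac1p M M'$. It is the
  kernel form of ridge regression on marker effects: with
  $\sigma_{g}^2 = p\,\sigma_a^2$ both give identical predictions, a fact the
  test suite checks against an explicit mixed-model-equation solve.
* **HGBLUP** partitions the genome into non-overlapping blocks of $L$
  consecutive SNPs (a trailing block shorter than $L$ at a chromosome end
  is kept), enumerates the distinct haplotype alleles per block, and uses
  $H = \tfrac1p \sum_k X_k X_k'$ where $X_k$ counts allele copies. With
  $\sigma_g^2 = p\,\sigma_h^2$ this is exactly the model with iid haplotype
  effects of variance $\sigma_h^2$.
* **EGBLUP / LEGBLUP** add a second, digenic-epistasis kernel
  $$ G_2 = \frac{1}{2q} \sum_k \big[(M_kM_k')\circ(M_kM_k') -
     (M_k{\circ}M_k)(M_k{\circ}M_k)'\big], \qquad
     q = \sum_k \binom{p_k}{2}, $$
  over all marker pairs (EGBLUP: the whole genome is one block) or only
  pairs inside haplotype blocks (LEGBLUP). Algebraically the bracketed term
  equals $2 F_kF_k'$ where the columns of $F_k$ are the pairwise products
  of marker columns, so $G_2 = \tfrac1q\sum_k F_kF_k'$ and
  $\sigma_{g_2}^2 = q\,\sigma_{aa}^2$ matches the explicit epistatic ridge
  model. Higher-order local epistasis is available through entrywise powers
  of $G_1$ (`hadamardPowerKernel()`), taken as plain Hadamard powers
  without subtracting lower-order overlap — the digenic-corrected form is
  used only at order two, mirroring the construction the kernels derive
  from.

**No allele-frequency centering** is applied by default: the transform
below is stated in raw counts, and centering changes the epistatic kernels
materially (products of centered columns are not the coding of pairwise
genotype classes). A centering switch exists on `additiveKernel()` for
users who want the conventional scaled kernel; everything in this package's
tests runs uncentered. Because subset products depend on which allele is
counted, epistatic kernels are coding-dependent; VCF input counts the
alternate allele, matrix input is taken as-is.

## The transform: why haplotype models fit local epistasis

For one fully homozygous block of $p$ markers let $Z$ be the
$n \times (2^p{-}1)$ design whose columns are the products of marker-code
columns over every non-empty marker subset (ordered by size, then
lexicographically). An order-$t$ column has entries $2^t$ for homozygous
carriers of all $t$ markers and 0 otherwise. Let $X$ be the haplotype
design after dropping the redundant all-zero-code allele (every row of the
full design sums to 2, so one column is expressible through the others and
the intercept). Then there is a $(2^p{-}1)\times s$ matrix $V$ with
$X = ZV$:

* if every nonzero-code haplotype occurs ($s = 2^p - 1$), the submatrix
  $\tilde Z$ of first-carrier representative rows is invertible and
  $V = \tilde Z^{-1}\tilde X$ with $\tilde X = 2I$;
* otherwise $\tilde Z$ has full row rank and $V = W\tilde X$ for any right
  inverse $W$; the Moore–Penrose pseudoinverse is used for determinism.

`computeTransform()` verifies $X = ZV$ on all rows (integer-valued designs;
the exactness tolerance is $10^{-10}$ absolute) and returns the implied
effect covariance $VV'\sigma_h^2$: the haplotype model is the full
local-epistasis model with *correlated* effects. Within the transform the
retained alleles are ordered by decreasing haplotype string, which makes
the reported $V$ independent of sample order and puts the all-carrier
allele first. With heterozygous loci a design row can hold two entries
equal to 1 and no $V$ exists in general;
`checkHeterozygousObstruction()` builds the candidate $V$ from the
homozygous individuals and reports the rows (individuals heterozygous at
two or more block loci) where $ZV \ne X$.

The canonical covariance (`blockEffectCovariance()`) is computed from the
synthetic design of *all* $2^p$ homozygous genotypes rather than from an
observed sample, so it is sample-independent. It has a closed structure
that the tests exploit as an independent oracle: the additive block is the
identity and every order-$t$ variance equals $4^{1-t}(2^t-1)\sigma_h^2$ —
hence additive : digenic $= 1 : 3/4 = 4{:}3$ for every block size.
`adjustVarianceRatio()` moves to another ratio (e.g. 3:1) by scaling all
epistatic variances with one common factor, implemented as a congruence
with a diagonal matrix, which provably preserves additive variances, all
correlations, the ratios among epistatic variances, and positive
semi-definiteness (the eigenvalue-clipping guard can therefore never
trigger; it remains as a safety net).

## Estimation

REML is the default because it is deterministic and hence testable. A
single kernel is fitted by eigendecomposition and a one-dimensional profile
restricted likelihood in $\delta = \sigma_e^2/\sigma_g^2$ (optimized on the
log scale over $[10^{-9}, 10^9]$), which makes repeated cross-validation
fits cheap. Several kernels are fitted by average-information updates with
a safeguarded multiplicative fallback whenever a Newton step would leave
the parameter space or reduce the likelihood; iteration stops when the
relative change in the restricted log-likelihood falls below $10^{-8}$
(cap 500 iterations, non-convergence flagged on the result rather than
thrown). Components are floored at $10^{-10}\,\mathrm{var}(y)$ during
iteration and reported as 0 below $10^{-6}$ of the total variance. Every
kernel receives a diagonal jitter of $10^{-8}$ times its mean diagonal
before factorization, since $VV'$-type kernels can be singular.

A Gibbs sampler is provided for parity with Bayesian implementations of
these models. Each kernel is re-expressed through its eigenvectors as a
ridge regression; variance components get scaled-inverse-$\chi^2$ priors
with 5 degrees of freedom and scales chosen so the prior mode equals half
the phenotypic variance split equally across components (defaults of this
package — reference settings for such analyses are rarely reported).
Posterior means are reported; predictions for unphenotyped individuals use
the posterior-mean components in the BLUP equations.

Prediction is transductive: kernels are built once on train and test
individuals jointly, and held-out genetic values come from the train × test
kernel blocks, the standard genomic-prediction cross-validation setup.

## The trait simulator

Real breeding panels are not redistributable here, so the package
generates synthetic inbred panels with a founder-mosaic model: per
chromosome, `nFounders` (default 8) random founder haplotypes are drawn
and each line's doubled haplotype is a crossover mosaic with per-interval
recombination probability `recombRate` (default 0.05, i.e. mean segments
of 20 markers). Defaults were chosen to resemble a multi-family doubled-
haploid crop panel: a few hundred lines, 10 chromosomes, limited haplotype
diversity per block and appreciable local linkage disequilibrium — the
regime in which haplotype alleles are informative. The model does *not*
reproduce population structure, allele-frequency spectra, or long-range LD
of any real panel, so passing tests demonstrate correctness of the
machinery and the qualitative model ordering, not empirical accuracies on
real data. Monomorphic markers are re-drawn (with a deterministic
alternating-allele fallback after 20 attempts).

Traits follow six architectures crossed with a target heritability and an
additive : digenic variance ratio (4:3 — the canonical ratio implied by the
transform — or 3:1 to weaken epistasis):

1. additive only, iid;
2. additive + global digenic epistasis at 1000 random QTL pairs, iid
   (the magnitude of the global digenic variance relative to
   $\sigma_a^2$ is set by the configured ratio — a package default, as no
   reference value exists);
3. additive + local digenic inside QTL blocks, iid;
4. all orders of local epistasis, iid, variances from the diagonal of the
   canonical covariance (keeping scenarios 4 and 6 comparable; an
   independence-only specification leaves the higher-order variance
   profile open, and the canonical diagonal is the natural choice);
5. local digenic with the correlated canonical covariance truncated to
   subsets of size ≤ 2;
6. all orders with the full correlated covariance $VV'\sigma_h^2$.

QTL are sampled uniformly without replacement, 100 per chromosome by
default (1000 genome-wide on a 10-chromosome map); for local scenarios
each chromosome's QTL are grouped into consecutive runs of length uniform
on $\{2,\dots,5\}$, and a trailing single QTL — which admits no local
epistasis — is merged into the previous block (chromosome-end handling is
a package choice). The additive effect variance is fixed at 1; only ratios
matter once phenotypes are formed as $y = g + e$ with
$\sigma_e^2 = \frac{1-h^2}{h^2}\,\widehat{\mathrm{var}}(g)$ computed from
the realized genetic variance, which centers the realized heritability at
the target.

## Evaluation

`runComparison()` performs repeated balanced $k$-fold cross-validation
(default $k = 5$, 20 repeats — the repeat count is configurable; accuracy
figures in this field rarely state it). Fold assignments are shared across
models within a repeat, giving a paired comparison, and kernels are
computed once per (model, window) on the full panel. Accuracy is the
Pearson correlation between predicted and true simulated genetic values
(simulated data) or observed phenotypes (empirical data, "predictive
ability"); the standard error is the standard deviation over fold-level
estimates divided by the square root of their number.

## Problem sizes and numerical choices

The test suite runs brute-force oracle comparisons on panels of up to 10
individuals and blocks of up to 4 markers (tolerance $10^{-10}$), model
equivalences at $n = 30$ (tolerance $10^{-6}$), simulator calibration at
$n = 500$ with 20 trait replicates, and the model-ordering comparison on a
400-line, 1500-marker panel with 20 replicates and windows 3–5 — sizes
chosen so the full suite completes in a few minutes while keeping
Monte-Carlo error well below the effects being tested. Epistatic designs
are capped at blocks of 12 markers ($2^{12}-1$ columns); the simulator's
default block range 2–5 stays far below this.

## Limitations

* Fixed-length windows only; LD-based or map-distance block definitions
  are out of scope (the theory does not depend on the block definition,
  but empirical performance does).
* No dominance effects, pedigree relationships, fixed-effect covariates
  beyond the intercept, multi-trait or multi-environment models.
* Statistical phasing and genotype imputation are not implemented; unknown
  phase is handled by the 50/50 random orientation of heterozygous loci,
  and missing calls only by explicit per-marker mode/mean imputation.
* Hadamard-power kernels above order two inherit the overlap approximation
  discussed above.
* The heterozygous case has no exact transform; HGBLUP remains applicable
  as a kernel method, but its local-epistasis interpretation is only
  guaranteed for inbred data.
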