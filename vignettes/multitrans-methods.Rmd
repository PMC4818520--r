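---
title: "Multiple-testing correction for mixed-model GWAS: model, sampler, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-testing correction for mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitrans)
```

## The statistical problem

A genome-wide scan computes one association statistic per marker and
rejects wherever the pointwise p-value falls below a per-marker threshold
$u$.  Controlling the family-wise error rate (FWER) at level $\alpha$
means choosing $u$ so that, under the global null,
$\Pr(\min_i p_i \le u) = \alpha$.  Because markers in linkage
disequilibrium (LD) yield correlated statistics, the independence-based
Bonferroni ($u = \alpha/m$) and Šidák corrections are conservative; the
exact answer depends on the joint null distribution of all $m$
statistics.

Under the plain linear model with standardized phenotype and genotypes,
the null statistic vector is asymptotically multivariate normal with unit
variances and $\mathrm{Cov}(S_i, S_j) = \mathrm{Cor}(X_i, X_j)$ — the
genotype correlation.  Sampling from that MVN and recording each
replicate's minimum pointwise p-value realizes the FWER integral by Monte
Carlo.

Mixed-model GWAS breaks this identity.  With
$y = \mu\mathbf{1} + X_i\beta_i + g + e$, $g \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$, the generalized-least-squares statistic has

$$\mathrm{Cov}(S_i, S_j)
  = \mathrm{Cor}(\hat V^{-1/2} X_i,\; \hat V^{-1/2} X_j) \equiv r^M_{ij},
  \qquad \hat V = \hat\sigma_g^2 K + \hat\sigma_e^2 I .$$

The package's central object is therefore the correlation matrix of
genotypes transformed by the symmetric inverse square root of the fitted
phenotype covariance.  At $\hat\sigma_g^2 = 0$ it reduces exactly to the
raw genotype correlation, recovering the linear-model machinery.

Permutation — the classical gold standard — is *invalid* here: permuting
phenotypes destroys the covariance structure the model asserts, so
"null" replicates are not draws from the null.  The valid resampling
scheme is the parametric bootstrap (null phenotypes from $N(0, \hat V)$,
full rescan per replicate), which this package implements as the
reference, and which the MVN sampler approximates at a cost independent
of the number of individuals.

## Pipeline and parameters

`run_multitrans()` chains: marker filtering (defaults MAF $\ge 0.05$,
missingness $\le 0.10$, the field's standard quality-control rule) →
column standardization (mean 0, variance 1 with denominator $n$, so a
correlation is an inner product over $n$; missing dosages are mean-imputed
first) → kinship $K = XX^\top/m$ → REML variance components → transformed
band → sliding-window MVN sampling → empirical threshold.

Parameters that matter:

* **`window`** (markers; default 1000, 100 offered for speed): how many
  predecessors each statistic is conditioned on.  Correct whenever
  statistics further apart than the window are uncorrelated after the
  transformation — the *local LD assumption*.  It is conservative: ignored
  positive correlation can only overstate the effective number of tests.
  Windows never span chromosome boundaries.
* **`n_samples`** (default $10^5$ in `run_multitrans()`, $10^6$ in the
  command-line wrapper): MVN replicates.  The quantile's Monte-Carlo
  standard error is always reported (`mc_se`) so users can size this; at
  $\alpha = 0.05$ the relative SE of the threshold is roughly
  $1.5\%\,(10^5/s)^{1/2}$ on weakly correlated panels.
* **`alpha`**: FWER level; report grids echo the 0.1 %–10 % range.
* **`method`** `"REML"` (default) or `"ML"`: one spectral decomposition of
  $K$, then a 1-D profile likelihood over $\log\delta$,
  $\delta = \sigma_e^2/\sigma_g^2$, on $[-10, 10]$ (natural log) with a
  100-point grid refined by Brent's method to $10^{-6}$; boundary optima
  are reported as heritability $\approx$ 0 or 1 with a warning.

## Numerical design of the sampler

The band entry $(i, d)$ holds the sample correlation of transformed
markers $i$ and $i-d$.  Two numerical facts shape the sampler; both only
bite when the window size $w$ is not small relative to the number of
individuals $n$:

1. **Estimation noise.**  Each band entry is a sample correlation with
   standard error $\approx 1/\sqrt n$.  Conditioning a $w$-dimensional
   Gaussian system on pure noise overfits: as $w \to n$ the apparent
   explained variance $\rho^\top R^{-1}\rho \to 1$ spuriously and the
   conditional variance collapses.  `windowed_correlation()` therefore
   zeroes band entries below `noise_floor` (default $2/\sqrt n$, two
   standard errors of a null correlation).  This is the classical
   banding/hard-thresholding covariance estimator, and it is exactly
   aligned with the local-LD assumption: the truth is banded, the noise is
   not.  Pass `noise_floor = 0` to keep raw correlations (used by the
   exact-oracle tests).
2. **Self-consistency.**  A thresholded band is no longer the restriction
   of any single positive-semidefinite matrix, and a chain that solves
   each conditional against the *claimed* band accumulates variance drift
   (marginal variances several-fold too large in our experiments, which
   destroys tail quantiles).  `sample_null_statistics()` instead
   conditions each marker only on predecessors inside its non-zero band
   support and solves the coefficients against the **realized** covariance
   of the chain so far, with the band entries as targets; the conditional
   variance is then set so every marginal is exactly 1.  When the band is
   exactly consistent (an AR(1) band, or the full Gram with
   `window >= m - 1` and `noise_floor = 0`) this provably coincides with
   the textbook conditional sampler, which the test suite verifies against
   dense Cholesky sampling.  Rank-deficient window blocks (inevitable once
   $w \ge n$) are handled by an eigendecomposition solve with the spectrum
   clipped at `ridge` relative tolerance; perfectly predicted markers
   (exact duplicates) receive the `min_conditional_var` floor
   ($10^{-8}$), a valid and slightly conservative draw.

The per-marker cost is one small solve plus an $O(w s)$ update across all
$s$ replicates; only the running maximum $|S|$ per replicate is stored.

## Statistic and p-value convention

The scan reports statistics on the z scale, but the marginal p-value is
computed from the exact Student-$t$ null of the transformed-space
correlation ($\mathrm{df} = n - 2$) and mapped back through the normal
quantile.  Both identities then hold simultaneously:
`pvalue == 2 * (1 - pnorm(abs(stat)))` exactly, and per-marker p-values
are exactly uniform under the null at finite $n$.  This matters for the
package's central cross-check: the bootstrap's minimum-p distribution and
the MVN sampler's (whose margins are exactly normal) then differ only
through their dependence structure, not through marginal miscalibration —
with a plain normal p-value on the $t$-distributed statistic at
$n \approx 100$, the two would disagree by tens of percent in the far
tail for reasons that have nothing to do with the method.  The residual
difference between the sampler and the bootstrap is the finite-$n$ gap
between the Gaussian copula and the bootstrap's spherical-projection
copula; it shrinks with $n$ and is the same phenomenon as the few-percent
discrepancies visible when both are run on real panels.

## The threshold and its uncertainty

`per_marker_threshold()` returns the empirical $\alpha$-quantile of the
per-replicate minimum p-values (order statistic $\lceil\alpha s\rceil$,
lower tie value — the conservative side), with a Monte-Carlo standard
error obtained by mapping the binomial error of the tail probability
through a local density estimate of the min-p distribution.
`family_wise_error()` inverts the relationship, returning the realized
FWER at any pointwise threshold with an exact binomial confidence
interval.  Thresholds always satisfy
$\alpha/m \lesssim u \le \alpha$ up to Monte-Carlo error.

## What the synthetic generator does and does not emulate

`simulate_genotypes()` produces the two features of real panels that
drive the problem: *population structure* (Balding–Nichols: ancestral
frequency $p_0 \sim U(\text{maf\_range})$, per-population frequencies
$\sim \mathrm{Beta}(p_0(1-F)/F, (1-p_0)(1-F)/F)$ at divergence $F$) and
*local LD* (each haplotype copies its previous allele with probability
`ld_rho`, a first-order Markov chain with geometric correlation decay).
Defaults — two populations, $F = 0.15$, `ld_rho` 0.7, MAF in (0.1, 0.5),
two chromosomes — describe a moderately structured model-organism panel.
`simulate_phenotype()` draws $y = g + e$ with $g \sim N(0, h^2 K)$ and
$e \sim N(0, (1-h^2) I)$; $h^2$ is the population parameter and the
sample variance is deliberately not renormalized.

Two interactions of the generator's knobs are worth knowing.  First, the
copy process dilutes differentiation: a copied allele ignores the new
marker's population frequency, so high `ld_rho` weakens the realized
structure — strongly related panels are best emulated with high `fst`
and moderate `ld_rho`.  Second, a kinship matrix *estimated* from $m$
markers at sample size $n$ carries Wishart noise with eigenvalue spread
$(1 \pm \sqrt{n/m_\mathrm{eff}})^2$; when the scanned markers are a
non-negligible fraction of the kinship panel, transforming by
$\hat V^{-1/2}$ partially whitens their own estimation noise, an effect
absent at real whole-genome scale.  The shipped checks therefore
estimate kinship from a chromosome disjoint from the scan region when
the point under test is the effect of true relatedness.

Not emulated: coalescent-exact LD decay, admixture gradients, inbred
strain replicates (kinship entries near 1), non-normal phenotypes,
case-control traits.  Passing tests on these panels therefore shows the
machinery is correct under structure and local LD of realistic magnitude;
it does not certify behavior on panels whose kinship is nearly singular
or whose traits are heavily skewed.

One empirical caveat discovered while validating the permutation
baseline: on these Balding–Nichols panels, naive permutation with
per-permutation variance-component refit produces *conservative* pooled
p-values (the spurious refitted heritability down-weights
structure-aligned markers), not the anti-conservative inflation sometimes
reported for real inbred panels.  The invalidity of permutation under
structure — significant miscalibration in either direction — is what the
test suite asserts about the refit protocol; dramatic miscalibration is
easiest to provoke with the fixed-$\hat V$ protocol on strain-like
panels.

## Problem sizes used in the shipped checks

The acceptance script analyzes a single $n = 100$, $m = 1000$ panel with
$10^5$ MVN samples and a $10^4$-replicate bootstrap; the test suite uses
panels between $m = 60$ and $m = 10^4$ markers and up to $10^5$ samples
per run.  These sizes were chosen so the whole suite completes in minutes
on one core while keeping every Monte-Carlo comparison's standard error
well below the effect it measures; all of them scale up unchanged.

## Known limitations

* Covariates beyond the intercept, multiple variance components, and
  exact per-marker REML refitting are out of scope; the statistic matches
  the common "fit the null variance components once" practice.
* The MVN approximation inherits the z-score asymptotics; for very small
  $n$ the Gaussian-copula gap against the bootstrap (a few percent on
  $n = 100$ panels) is the dominant error and no amount of sampling
  reduces it.
* The dense oracle sampler is limited to $m \le 5000$; it exists for
  validation, not production.
* Kinship is the standardized-genotype product $XX^\top/m$; alternative
  estimators can be supplied as files and are accepted verbatim after a
  symmetry check.
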