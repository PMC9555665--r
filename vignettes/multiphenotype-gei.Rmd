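---
title: "Kernel-based gene-environment interaction tests for rare variants with multiple phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based gene-environment interaction tests for rare variants with multiple phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpgei)
```

## The problem

A rare variant (minor allele frequency, MAF, at or below ~1%) carries too
little information to be tested on its own, so rare-variant association
methods aggregate all variants in a gene or region and test them jointly.
`mpgei` addresses a specific question in that setting: does the *effect of
the region's variants depend on an environmental exposure* — a
gene-environment interaction (GEI) — and does that interaction act on
*several correlated quantitative phenotypes at once* (GEI pleiotropy)?
The motivating application is gene-by-hemoglobin interaction on systolic and
diastolic blood pressure measured in the same individuals, but the machinery
is generic: any set of quantitative phenotypes, any continuous centered
exposure.

## Model and test statistic

For sample $i = 1,\dots,n$, region variants $j = 1,\dots,m$ and phenotypes
$k = 1,\dots,K$, the mixed model is

$$
y_k = X\alpha_k + GW\beta_k + EGW\gamma_k + \varepsilon_k,
$$

where $X$ is the covariate matrix (intercept first; the centered exposure is
one of its columns, so the environmental *main* effect is always adjusted
for), $G$ the $n \times m$ minor-allele count matrix, $W =
\mathrm{diag}(w_j)$ the variant weights, $E = \mathrm{diag}(E_i)$ the
centered exposure, $\beta_k$ fixed genetic main effects, and $\gamma_k$
random interaction effects. Stacking phenotypes,
$\mathrm{vec}(\Gamma) \sim \mathrm{MVN}(0,\ \sigma^2\, \Sigma_P \otimes I_m)$,
where the $K \times K$ *phenotype-space kernel* $\Sigma_P$ encodes how a
variant's interaction effect is shared across phenotypes. The null
hypothesis of no interaction anywhere in the region is $H_0: \sigma^2 = 0$,
tested by the variance-component score statistic

$$
Q = \mathrm{vec}(y-\hat\mu)^\top
\left\{(\hat\Sigma^{-1}\Sigma_P\hat\Sigma^{-1}) \otimes (EGWWG^\top E)\right\}
\mathrm{vec}(y-\hat\mu),
$$

which requires only the null fit: per-phenotype least squares on
$Z = (X, GW)$, residuals $y - \hat\mu$, and the residual covariance
$\hat\Sigma$ (cross-products of the per-phenotype residuals divided by
$n - \mathrm{rank}(Z)$). Under $H_0$, $Q$ follows a mixture
$\sum_u \lambda_u \chi^2_{1,u}$ whose weights are the nonzero eigenvalues of

$$
\Psi = \Sigma_P^{1/2}\hat\Sigma^{-1}\Sigma_P^{1/2} \otimes WG^\top E P E G W,
\qquad P = I_n - Z(Z^\top Z)^{-1}Z^\top .
$$

### The four kernels

| kernel | $\Sigma_P$ | assumption about interaction effects |
|---|---|---|
| Hom | $1_K 1_K^\top$ | identical across phenotypes |
| Het | $I_K$ | independent across phenotypes |
| PPK | $\hat\Sigma$ | share the phenotypes' own covariance |
| LPK | $\hat\Sigma^2$ | combines the $K$ single-phenotype statistics, ignoring correlation |

At $K = 1$ every kernel collapses to the single-phenotype GEI score test
($Q_k = \sum_j w_j^2 S_{jk}^2$ with per-variant scores
$S_{jk} = \sum_i E_i G_{ij}(y_{ik}-\hat\mu_{ik})/\hat\sigma_k^2$), and with
$\Sigma_P = \hat\Sigma^2$ the phenotype-space factor
$\hat\Sigma^{-1}\Sigma_P\hat\Sigma^{-1}$ is exactly $I_K$, so
$Q_{\mathrm{LPK}}$ equals the unscaled sum of the per-phenotype pieces.
Both identities are asserted in the test suite at $10^{-10}$ relative
tolerance.

### Numerical strategy

The Kronecker products above are *never* materialised. $Q$ is computed as
$\mathrm{tr}(A S^\top S)$ with $A = \hat\Sigma^{-1}\Sigma_P\hat\Sigma^{-1}$
and the $m \times K$ weighted score matrix $S = WG^\top E(y-\hat\mu)$; the
spectrum of $\Psi$ is the set of pairwise products of the $K$ eigenvalues of
$\Sigma_P^{1/2}\hat\Sigma^{-1}\Sigma_P^{1/2}$ and the $m$ eigenvalues of
$(EGW)^\top P (EGW)$, where the projection is applied through the
rank-revealing QR factorisation of $Z$ retained from the fit — the
$n \times n$ projector is never formed. The test suite verifies both against
brute-force materialisation on small instances.

Further numerical choices:

* **Least squares** uses pivoted QR (`lm.fit`), never $(Z^\top Z)^{-1}$.
  Numerically collinear weighted-genotype columns (for rare variants,
  typically duplicated singleton columns) are dropped from the *null design*
  with a warning but retained in the *interaction term under test*: removing
  them from the kernel would silently change the hypothesis.
* **Residual variance denominator** is the unbiased $n - \mathrm{rank}(Z)$;
  at study sizes ($n$ = thousands, $\mathrm{rank}(Z)$ < 50) the difference
  from the maximum-likelihood $n$ is far below Monte-Carlo resolution.
* **$\Sigma_P^{1/2}$** is the symmetric PSD square root with negative
  eigenvalues clipped at zero ($10^{-8}$ relative); any square root yields
  the same spectrum.
* **Eigenvalue truncation** at $10^{-10}\lambda_{\max}$ defines "nonzero
  eigenvalues" numerically. If everything is truncated the test is
  degenerate and the p-value is reported as 1.
* **Weights** default to the Beta(1, 25) density at the sample MAF,
  $w_j = 25(1-\mathrm{MAF}_j)^{24}$, recomputed on the analysed samples.
  Scaling all weights by $c$ scales $Q$ and every eigenvalue by $c^2$ and
  leaves the p-value unchanged (tested).

## Tail probabilities

P-values are upper-tail probabilities of $\sum_u \lambda_u \chi^2_{1,u}$,
computed by Kuonen's saddlepoint approximation: solve
$K'(\hat\zeta) = q$ for the cumulant generating function
$K(\zeta) = -\frac12\sum_u \log(1-2\zeta\lambda_u)$ by bracketed
root-finding on $(-\infty,\ 1/2\lambda_{\max})$ (the derivative is strictly
increasing, so the root is unique; the spectrum is pre-scaled to unit total,
making the result exactly scale-invariant), then apply the Lugannani-Rice
formula with Daniels' second-order cumulant correction. On few-term, skewed
spectra the first-order formula carries relative errors of several percent
at moderate p; the second-order term reduces this several-fold (verified
against Monte-Carlo and numerical-inversion oracles in the test suite), and
left-tail saddlepoints ($\hat\zeta < 0$) keep p-values near 1 accurate.
Three safety valves apply, in order:

1. a spectrum whose weights are all equal is a scaled $\chi^2_m$ and is
   evaluated *exactly*;
2. statistics within $10^{-4}$ of the null mean $\sum_u\lambda_u$ (where the
   saddlepoint root degenerates) are perturbed upward, conservatively;
3. if root-finding fails or the result leaves $(0, 1]$, a Liu-type
   four-moment match to a scaled noncentral chi-square takes over
   (`p_method = "fallback"`).

Reported p-values are clamped below at $10^{-300}$ rather than underflowing
to zero.

## The simulation engine

`simulate_genotypes()` emulates rare-variant region data without external
haplotype resources: site count $\sim$ Poisson(0.01/bp $\times$ 3000 bp,
about 30 sites), per-site population MAF drawn from a density
$\propto 1/p$ truncated to $[0.5/n,\ 0.01]$ (the neutral
site-frequency-spectrum shape, skewed toward very rare sites), genotypes
Binomial(2, MAF) under Hardy-Weinberg, monomorphic columns redrawn. This is
deliberately simple: **no linkage disequilibrium, no demography** — features
a coalescent simulator would add. Consequently, simulation results here
characterise the tests under idealised independent-site regions; empirical
power under realistic haplotype structure can differ.

`simulate_phenotypes()` generates $K = 4$ phenotypes per sample:
$\mathrm{sex} \sim$ Bernoulli(0.5) with effects $(0.1, 0.5, 0.1, 0.5)$
across phenotypes, age $\sim N(50, 25)$ with effect 0.05 and BMI
$\sim N(50, 25)$ with effect 0.1 — the second argument of $N(\cdot,\cdot)$
is a *variance* throughout (so both have standard deviation 5; reading 25 as
a standard deviation would make negative ages routine). Centered BMI is the
environmental exposure. A proportion $\theta$ of the region's variants
(rounded, at least one) is causal; causal variants carry main effects
$\beta_k = (0.1, 0.2, 0.1, 0.2)$ and, under the alternative, interaction
effects $\gamma_{jk} \sim N(0, 0.05^2)$ drawn independently per variant and
phenotype (heterogeneous pleiotropy), both confined to phenotypes flagged by
the indicators $l_k$. Errors are MVN with variance 4 for phenotype 1,
variance 1 for phenotypes 2-4, and constant pairwise correlation $\rho$.

Two generator decisions deserve emphasis:

* **Effects act on raw minor-allele counts, not on Beta-weighted
  genotypes.** With Beta(1, 25)-density weights (about 25 for rare sites)
  inside the generative sums, a causal carrier would shift its phenotype by
  several residual standard deviations per unit of exposure, and every
  alternative scenario would be detected with certainty at genome-wide
  significance — not a meaningful power regime. Applying effects to raw
  counts is the standard convention in region-based rare-variant simulation
  designs; the analysis weights are applied by the tests regardless. The
  printed-model reading remains available via
  `sim_config(weighted_effects = TRUE)`.
* **The error covariance** uses the unique standard structure consistent
  with "one high-variance phenotype plus equicorrelation": standard
  deviations $(2, 1, 1, 1)$ and constant correlation $\rho$; it is fully
  configurable (`var_first`, `var_rest`, `rho`).

Randomness is split over named substreams (covariates, causal-set choice,
interaction draws, errors) derived from one master seed, so, for example,
the alternative generator with `gamma_sd = 0` replays the null generator
bit-for-bit, and replicate $r$ of a study is reproducible in isolation.

## Study drivers and the scales used

`run_null_study()` draws several phenotype/covariate replicates per genotype
replicate (default 20, following the layered design of the original
experiments) and returns pooled p-values with uniform plotting positions for
QQ inspection; `run_power_study()` draws fresh genotypes and alternative
phenotypes per replicate and tabulates rejection fractions with Monte-Carlo
standard errors $\sqrt{\hat p(1-\hat p)/R}$. Both are deterministic given
their seed. `autoplot()` methods render the QQ panels and power bars.

The package's own validation runs these at deliberate desk scales: type-I
calibration at $n = 5000$, $\rho = 0.5$, 2000 pooled null replicates
(rejection at $\alpha = 0.05$ checked within three Monte-Carlo standard
errors, plus a Kolmogorov-Smirnov uniformity check at level 0.01), and power
scenarios at $n = 5000$ with 300-400 replicates each at
$\alpha = 2.5\times10^{-6}$ (the genome-wide threshold for ~20,000 genes)
or $\alpha = 0.05$. With these replicate counts a power estimate carries a
standard error of at most ~0.029.

## Known limitations

* Unrelated samples only: no kinship or mixed-model correction.
* Quantitative phenotypes only; all phenotypes share one design matrix.
* Biallelic variants; missing genotypes imputed to zero minor alleles
  (variants over 10% missing dropped).
* VCFs are read whole and filtered in memory — suitable for per-gene or
  per-chromosome files, not indexed random access across a biobank-scale
  genome.
* The genotype generator's independent-site design means simulated power
  should be read as characterising the idealised regime; region tests on
  real haplotypes, where rare alleles are correlated, can be easier or
  harder depending on LD with causal sites.

## A minimal session

```{r example}
g <- simulate_genotypes(n = 1000, seed = 42)
cfg <- sim_config(n = 1000, theta = 0.2, rho = 0.5)
sim <- simulate_phenotypes(g, cfg, alternative = TRUE, seed = 42)
gei_test(g, sim$pheno, sim$covariates, sim$env)
```
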