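# mpgei

Kernel-based gene-environment interaction (GEI) tests for rare variants
with one or several correlated quantitative phenotypes.

## What problem this solves

Individually, rare variants (minor allele frequency ≤ ~1%) are almost
uninformative, so rare-variant association methods test a whole gene or
region at once. `mpgei` asks whether the region's variants *interact with an
environmental exposure* — does the genetic effect depend on, say, BMI or
hemoglobin? — and lets that interaction act jointly on several phenotypes
measured in the same individuals (GEI pleiotropy, e.g. systolic and
diastolic blood pressure). Analysing the phenotypes together is usually more
powerful than testing them one at a time.

The package is for statistical geneticists and epidemiologists with
region-grouped genotypes (VCF), per-sample phenotype/covariate tables (TSV),
and a continuous exposure of interest.

## The statistic

For phenotypes $y_1,\dots,y_K$, covariates $X$ (including the centered
exposure), genotypes $G$, Beta(1,25)-density weights
$W = \mathrm{diag}(w_j)$, $w_j = 25(1-\mathrm{MAF}_j)^{24}$, and exposure
matrix $E = \mathrm{diag}(E_i)$, the model is

$$y_k = X\alpha_k + GW\beta_k + EGW\gamma_k + \varepsilon_k,
\qquad \mathrm{vec}(\Gamma) \sim \mathrm{MVN}(0,\ \sigma^2\,\Sigma_P \otimes I_m),$$

and $H_0\!: \sigma^2 = 0$ is tested with the score statistic

$$Q = \mathrm{vec}(y-\hat\mu)^\top\{(\hat\Sigma^{-1}\Sigma_P\hat\Sigma^{-1})
\otimes (EGWWG^\top E)\}\,\mathrm{vec}(y-\hat\mu),$$

whose null distribution is a mixture of 1-df chi-squares weighted by the
eigenvalues of
$\Psi = \Sigma_P^{1/2}\hat\Sigma^{-1}\Sigma_P^{1/2} \otimes WG^\top EPEGW$.
Four choices of the phenotype-space kernel $\Sigma_P$ give four tests:
**Hom** (all-ones: identical effects across phenotypes), **Het** (identity:
independent effects), **PPK** (the estimated phenotype covariance
$\hat\Sigma$) and **LPK** ($\hat\Sigma^2$, equivalent to summing the
single-phenotype statistics). P-values come from Kuonen's saddlepoint
approximation (second-order Lugannani-Rice), with exact evaluation for
degenerate spectra and a Liu-type moment-matching fallback. At $K=1$ all
kernels reduce to the single-phenotype GEI score test.

## Worked example

Simulate a 3 kb rare-variant region and four correlated phenotypes with
gene-BMI interactions on every phenotype, then test with all four kernels:

```r
library(mpgei)

g <- simulate_genotypes(n = 2000, seed = 42)
#> <genotype_region> simulated (1:1-3000)
#>   2000 samples x 37 variants, MAF in [0.00025, 0.00975]

cfg <- sim_config(n = 2000, theta = 0.2, rho = 0.5)   # 20% causal, correlation 0.5
sim <- simulate_phenotypes(g, cfg, alternative = TRUE, seed = 42)
gei_test(g, sim$pheno, sim$covariates, sim$env)
#>   region_id m_variants kernel statistic     p_value    p_method
#> 1 simulated         37    Hom  10110408 0.315260807 saddlepoint
#> 2 simulated         37    Het  50088298 0.000859252 saddlepoint
#> 3 simulated         37    PPK  31374494 0.014950152 saddlepoint
#> 4 simulated         37    LPK  36932449 0.622707050 saddlepoint
```

The heterogeneous (Het) and projection (PPK) kernels detect the simulated
interactions (the generator draws each variant's interaction effect
independently per phenotype, matching their assumptions), while the
homogeneous kernel — built for identical effects across phenotypes — and
LPK — which ignores the phenotype correlation — do not. The statistic's
magnitude is arbitrary (it scales with the squared weights); only the
p-value is comparable across settings.

Real data enter through `read_region_genotypes()` (VCF),
`read_sample_table()` / `read_region_table()` (TSV), and results leave via
`write_gei_results()`. Fitted objects support `tidy()` and `glance()`;
`run_power_study()` / `run_null_study()` results support `autoplot()`.
A command-line wrapper with `test`, `simulate`, `power` and `qq` subcommands
is installed at `exec/mpgei.R` inside the package directory.

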