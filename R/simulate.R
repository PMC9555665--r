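#' Simulation configuration for the GEI study designs
#'
#' Collects every generative parameter of the null and alternative phenotype
#' models so that simulation studies are fully reproducible from one object.
#' Defaults are the study conditions used throughout the power and
#' type-I-error experiments: n = 5000 samples, K = 4 phenotypes, a 3 kb
#' region of rare variants (MAF <= 0.01), causal proportion `theta`,
#' constant among-phenotype correlation `rho`, gene-BMI interaction effects
#' with standard deviation `gamma_sd` on the phenotypes flagged by `l`.
#'
#' @param n Sample count.
#' @param K Number of phenotypes.
#' @param theta Proportion of region variants that are causal (0, 1].
#' @param rho Among-phenotype error correlation, in \[0, 1).
#' @param l Binary pleiotropy indicators (length K): phenotype k receives
#'   genetic main effects and interactions only when `l[k] == 1`.
#' @param beta_main Genetic main-effect sizes per phenotype.
#' @param gamma_sd Standard deviation of the per-variant, per-phenotype
#'   interaction effects (drawn independently, i.e. heterogeneous pleiotropy).
#' @param sex_coef,age_coef,bmi_coef Fixed covariate effects.  Sex is
#'   Bernoulli(`sex_prob`); age and BMI are normal with the given means and
#'   standard deviations.
#' @param sex_prob,age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions.
#' @param var_first,var_rest Error variances: `var_first` for phenotype 1,
#'   `var_rest` for the remaining phenotypes; all pairwise error correlations
#'   equal `rho`.
#' @param rare_maf_max Rare-variant MAF threshold.
#' @param region_bp Region length in base pairs.
#' @param variant_density Expected variants per base pair.
#' @param weighted_effects If `TRUE`, the generative main and interaction
#'   effects act on Beta-density-weighted genotypes `G %*% W` instead of raw
#'   minor-allele counts.  The default is `FALSE`: with rare-variant weights
#'   of order 25 inside the generative sums, every alternative scenario is
#'   detected with certainty at genome-wide significance, which is not a
#'   meaningful power regime; effects on raw counts are the standard
#'   simulation convention for region-based rare-variant tests (the analysis
#'   weights are applied by the tests regardless).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 5000, K = 4, theta = 0.2, rho = 0.5,
                       l = rep(1L, K),
                       beta_main = c(0.1, 0.2, 0.1, 0.2),
                       gamma_sd = 0.05,
                       sex_coef = c(0.1, 0.5, 0.1, 0.5),
                       age_coef = 0.05, bmi_coef = 0.1,
                       sex_prob = 0.5, age_mean = 50, age_sd = 5,
                       bmi_mean = 50, bmi_sd = 5,
                       var_first = 4, var_rest = 1,
                       rare_maf_max = 0.01, region_bp = 3000,
                       variant_density = 0.01, weighted_effects = FALSE) {
  if (theta <= 0 || theta > 1) abort("theta must be in (0, 1]")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  l <- as.integer(l)
  if (length(l) != K || !all(l %in% c(0L, 1L))) {
    abort("l must be K binary pleiotropy indicators")
  }
  rep_k <- function(x) rep_len(as.numeric(x), K)
  structure(
    list(n = as.integer(n), K = as.integer(K), theta = theta, rho = rho,
         l = l, beta_main = rep_k(beta_main), gamma_sd = gamma_sd,
         sex_coef = rep_k(sex_coef), age_coef = age_coef, bmi_coef = bmi_coef,
         sex_prob = sex_prob, age_mean = age_mean, age_sd = age_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         var_first = var_first, var_rest = var_rest,
         rare_maf_max = rare_maf_max, region_bp = as.integer(region_bp),
         variant_density = variant_density,
         weighted_effects = isTRUE(weighted_effects)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> n = %d, K = %d, theta = %.2f, rho = %.2f, l = (%s)\n",
              x$n, x$K, x$theta, x$rho, paste(x$l, collapse = ",")))
  invisible(x)
}

#' Error covariance implied by a simulation configuration
#'
#' Phenotype 1 has error variance `var_first`, the others `var_rest`, and all
#' pairwise error correlations equal `rho` (so the covariance between
#' phenotype 1 and any other is `rho * sqrt(var_first * var_rest)`).
#'
#' @param cfg A [sim_config()].
#' @return The K x K generative error covariance.
#' @export
sim_error_covariance <- function(cfg) {
  sds <- sqrt(c(cfg$var_first, rep(cfg$var_rest, cfg$K - 1L)))
  R <- matrix(cfg$rho, cfg$K, cfg$K)
  diag(R) <- 1
  diag(sds) %*% R %*% diag(sds)
}

#' Simulate a region of rare-variant genotypes
#'
#' A stand-in for coalescent haplotype data: sites are placed independently
#' (no linkage disequilibrium) at Poisson-distributed density along the
#' region, per-site population MAFs are drawn from a rare-skewed spectrum
#' with density proportional to 1/p truncated to \[0.5/n, `maf_max`\]
#' (the neutral site-frequency-spectrum shape), and genotypes are sampled
#' per site as Binomial(2, MAF) under Hardy-Weinberg equilibrium.
#' Monomorphic columns are redrawn so every variant is polymorphic.
#'
#' @param n Sample count (>= 2).
#' @param region_bp Region length in base pairs.
#' @param maf_max Upper truncation of the population MAF spectrum.
#' @param variant_density Expected polymorphic sites per base pair.
#' @param seed Optional integer seed (local to this call).
#' @param region_id,chrom,start Metadata for the returned region.
#' @return A [genotype_region()]; `$maf` holds the realised sample MAFs.
#' @export
simulate_genotypes <- function(n, region_bp = 3000, maf_max = 0.01,
                               variant_density = 0.01, seed = NULL,
                               region_id = "simulated", chrom = "1",
                               start = 1L) {
  if (n < 2) abort("need at least two samples")
  with_seed(seed, {
    m <- 0L
    for (try in 1:100) {
      m <- rpois(1L, variant_density * region_bp)
      if (m >= 1L) break
    }
    if (m < 1L) abort("could not realise any variant site")
    p_min <- 0.5 / n
    if (p_min >= maf_max) abort("n too small for the requested maf_max")
    maf_pop <- p_min * (maf_max / p_min)^runif(m)   # density ~ 1/p, truncated
    counts <- matrix(rbinom(n * m, 2L, rep(maf_pop, each = n)), nrow = n)
    for (try in 1:200) {
      bad <- which(colSums(counts) == 0 | colMeans(counts) / 2 > 0.5)
      if (length(bad) == 0L) break
      counts[, bad] <- rbinom(n * length(bad), 2L,
                              rep(maf_pop[bad], each = n))
    }
    if (any(colSums(counts) == 0)) {
      abort("could not realise polymorphic rare sites; increase n or maf_max")
    }
    positions <- sort(sample.int(region_bp, m, replace = FALSE)) + start - 1L
    genotype_region(counts,
                    variant_ids = paste0("sim", seq_len(m)),
                    positions = positions, region_id = region_id,
                    chrom = chrom, start = start,
                    end = start + region_bp - 1L)
  })
}

#' Simulate correlated phenotypes with optional gene-environment interactions
#'
#' Generates K quantitative phenotypes for the samples of a genotype region
#' under the null (covariates + weighted genetic main effects + correlated
#' errors) or the alternative (additionally, gene-BMI interaction effects
#' drawn independently per causal variant and phenotype).  Centered BMI is
#' the environmental exposure and doubles as a covariate.
#'
#' Each phenotype k follows
#' \deqn{y_{ik} = c^{sex}_k sex_i + 0.05\, age_i + 0.1\, bmi_i
#'   + l_k \sum_{j \in causal} G_{ij} \beta_k
#'   + l_k \sum_{j \in causal} E_i G_{ij} \gamma_{jk} + \varepsilon_{ik}}
#' with \eqn{\gamma_{jk} \sim N(0, \gamma_{sd}^2)} (alternative only) and
#' errors \eqn{\varepsilon_i \sim MVN(0, \Sigma)} from
#' [sim_error_covariance()].  With `cfg$weighted_effects = TRUE` the causal
#' genotypes enter through `G_{ij} w_j` instead (Beta-density weights at the
#' realised sample MAFs).
#'
#' Randomness is split over named substreams (covariates, causal-set choice,
#' interaction effects, errors) derived from `seed`, so the alternative
#' generator with `gamma_sd = 0` reproduces the null generator exactly.
#'
#' @param geno A [genotype_region()] (its realised sample MAFs define the
#'   variant weights used in the generative model).
#' @param cfg A [sim_config()]; `cfg$n` must match the region.
#' @param alternative Draw interaction effects? (`FALSE` = null model.)
#' @param seed Optional integer master seed (local to this call).
#' @return A list of class `gei_sim`: `pheno` (tibble, n x K), `covariates`
#'   (tibble: sex, age, bmi with bmi centered), `env` (centered BMI),
#'   `causal` (indices of causal variants), `gamma` (causal x K interaction
#'   effects; zeros under the null), `geno`, `config`.
#' @export
simulate_phenotypes <- function(geno, cfg, alternative = FALSE, seed = NULL) {
  stopifnot(inherits(geno, "genotype_region"), inherits(cfg, "sim_config"))
  G <- geno$counts
  n <- nrow(G)
  m <- ncol(G)
  if (n != cfg$n) abort("cfg$n does not match the genotype region")
  K <- cfg$K
  if (is.null(seed)) seed <- sample.int(2^30, 1L)

  covs <- with_seed(substream_seed(seed, "covariates"), {
    list(sex = rbinom(n, 1L, cfg$sex_prob),
         age = rnorm(n, cfg$age_mean, cfg$age_sd),
         bmi = rnorm(n, cfg$bmi_mean, cfg$bmi_sd))
  })
  e <- covs$bmi - mean(covs$bmi)

  n_causal <- max(1L, round(cfg$theta * m))
  causal <- with_seed(substream_seed(seed, "causal"),
                      sort(sample.int(m, min(n_causal, m))))

  gamma <- matrix(0, length(causal), K)
  if (alternative && cfg$gamma_sd > 0) {
    gamma <- with_seed(substream_seed(seed, "gamma"),
                       matrix(rnorm(length(causal) * K, 0, cfg$gamma_sd),
                              length(causal), K))
  }

  Sigma <- sim_error_covariance(cfg)
  eps <- with_seed(substream_seed(seed, "errors"),
                   matrix(rnorm(n * K), n, K) %*% chol(Sigma))

  Gc <- G[, causal, drop = FALSE]
  wc <- if (cfg$weighted_effects) beta_weights(geno$maf)[causal] else
    rep(1, length(causal))
  burden <- as.vector(Gc %*% wc)          # summed causal genotypes
  y <- matrix(0, n, K)
  for (k in seq_len(K)) {
    y[, k] <- cfg$sex_coef[k] * covs$sex + cfg$age_coef * covs$age +
      cfg$bmi_coef * covs$bmi +
      cfg$l[k] * cfg$beta_main[k] * burden +
      cfg$l[k] * e * as.vector(Gc %*% (wc * gamma[, k])) +
      eps[, k]
  }
  colnames(y) <- paste0("y", seq_len(K))

  structure(
    list(pheno = as_tibble(y),
         covariates = tibble(sex = covs$sex, age = covs$age, bmi = e),
         env = e, causal = causal, gamma = gamma, geno = geno, config = cfg),
    class = "gei_sim"
  )
}

#' @export
print.gei_sim <- function(x, ...) {
  cat(sprintf("<gei_sim> %d samples, %d phenotypes, %d causal of %d variants\n",
              nrow(x$pheno), ncol(x$pheno), length(x$causal),
              ncol(x$geno$counts)))
  invisible(x)
}
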