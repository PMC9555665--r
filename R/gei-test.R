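#' Multiphenotype GEI score statistic for one kernel
#'
#' Computes the variance-component score statistic
#' \deqn{Q = \mathrm{vec}(y-\hat\mu)^\top\{(\hat\Sigma^{-1}\Sigma_P
#'   \hat\Sigma^{-1})\otimes(EGWWG^\top E)\}\mathrm{vec}(y-\hat\mu)}
#' for the null hypothesis of no gene-environment interaction in the region,
#' together with the eigenvalue spectrum of the matrix whose mixture of
#' 1-df chi-squares is the null law of Q, and the tail p-value.
#'
#' @param fit A [fit_gei_null()] object.
#' @param geno The [genotype_region()] used in the fit.
#' @param env Centered environmental exposure vector (must already be
#'   adjusted for as a covariate column of the null design; a warning is
#'   issued otherwise).
#' @param kernel Kernel kind (`"Hom"`, `"Het"`, `"PPK"`, `"LPK"`) or a
#'   K x K kernel matrix.
#' @param weights Per-variant weights; defaults to [beta_weights()] at the
#'   region's sample MAFs (must match the weights used in the fit).
#'
#' @details The Kronecker product is never materialised: Q is evaluated as
#'   \eqn{\mathrm{tr}(A S^\top S)} with
#'   \eqn{A = \hat\Sigma^{-1}\Sigma_P\hat\Sigma^{-1}} and the m x K weighted
#'   per-variant score matrix \eqn{S = WG^\top E (y - \hat\mu)}, and the
#'   spectrum as all pairwise products of the eigenvalues of the K x K factor
#'   \eqn{\Sigma_P^{1/2}\hat\Sigma^{-1}\Sigma_P^{1/2}} and of the m x m factor
#'   \eqn{(EGW)^\top P (EGW)} with P the null-design projector (applied
#'   through the stored QR factorisation, never as an n x n matrix).
#'   Eigenvalues below \eqn{10^{-10}\lambda_{max}} are truncated.
#'
#' @return An object of class `gei_result`: `Q`, `eigenvalues`, `p_value`,
#'   `p_method` (`"saddlepoint"` or `"fallback"`), `kernel`, `m_variants`,
#'   `score_components` (the m x K matrix S).
#' @export
gei_score_test <- function(fit, geno, env, kernel = "Het", weights = NULL) {
  stopifnot(inherits(fit, "gei_null_fit"), inherits(geno, "genotype_region"))
  G <- geno$counts
  if (is.null(weights)) weights <- beta_weights(geno$maf)
  e <- as.numeric(env)
  if (length(e) != fit$n) abort("environment length must equal sample count")

  K <- fit$K
  if (is.matrix(kernel)) {
    Sigma_P <- kernel
    kernel_label <- "custom"
    check_psd(Sigma_P, "kernel")
  } else {
    kernel_label <- normalize_kernel_kind(kernel)
    Sigma_P <- build_kernel(kernel_label, Sigma_hat = fit$Sigma_hat, K = K)
  }
  if (!all(dim(Sigma_P) == c(K, K))) abort("kernel must be K x K")
  if (kappa(fit$Sigma_hat) > 1e12) {
    abort("estimated phenotype covariance is numerically singular; remove duplicated phenotypes")
  }

  Si <- solve(fit$Sigma_hat)
  A <- Si %*% Sigma_P %*% Si

  # Q = tr(A S^T S) with S = W G^T E resid (m x K)
  S <- weights * crossprod(G * e, fit$resid)
  Q <- sum(A * crossprod(S))
  Q <- max(Q, 0)

  # spectrum: pairwise products of the K x K and m x m factor eigenvalues
  C <- sweep(G * e, 2L, weights, `*`)              # E G W, n x m
  CtPC <- crossprod_projected(fit, C)
  root <- sym_sqrt(Sigma_P)
  kern_fac <- root %*% Si %*% root
  a <- eigen((kern_fac + t(kern_fac)) / 2, symmetric = TRUE,
             only.values = TRUE)$values
  b <- eigen(CtPC, symmetric = TRUE, only.values = TRUE)$values
  lam <- as.vector(outer(pmax(a, 0), pmax(b, 0)))
  lam_max <- max(lam, 0)
  lam <- sort(lam[lam > 1e-10 * lam_max], decreasing = TRUE)

  if (length(lam) == 0L) {
    tail <- list(p = 1, method = "fallback")
  } else {
    tail <- mixture_pvalue(Q, lam)
  }

  structure(
    list(Q = Q, eigenvalues = lam, p_value = tail$p, p_method = tail$method,
         kernel = kernel_label, m_variants = ncol(G),
         score_components = S, region_id = geno$region_id,
         phenotype_names = fit$phenotype_names),
    class = "gei_result"
  )
}

#' Single-phenotype GEI score test
#'
#' The score test of gene-environment interaction for one quantitative
#' phenotype: \eqn{Q_k = \sum_j w_j^2 S_{jk}^2} with per-variant scores
#' \eqn{S_{jk} = \sum_i E_i G_{ij}(y_{ik}-\hat\mu_{ik})/\hat\sigma^2_k}, whose
#' null law is the mixture of 1-df chi-squares weighted by the nonzero
#' eigenvalues of \eqn{WG^\top E P E G W / \hat\sigma^2_k}.  Identical to the
#' multiphenotype heterogeneous-kernel test applied to that phenotype alone.
#'
#' @inheritParams gei_score_test
#' @param phenotype Index or name of the phenotype to test.
#' @return A `gei_result` with kernel label `"single:<name>"`.
#' @export
single_phenotype_gei_test <- function(fit, geno, env, phenotype = 1L,
                                      weights = NULL) {
  stopifnot(inherits(fit, "gei_null_fit"))
  if (is.character(phenotype)) {
    phenotype <- match(phenotype, fit$phenotype_names)
  }
  k <- as.integer(phenotype)
  if (is.na(k) || k < 1L || k > fit$K) abort("unknown phenotype")
  G <- geno$counts
  if (is.null(weights)) weights <- beta_weights(geno$maf)
  e <- as.numeric(env)

  s2 <- fit$sigma2[[k]]
  Sk <- as.vector(crossprod(G * e, fit$resid[, k])) / s2
  Q <- sum(weights^2 * Sk^2)

  C <- sweep(G * e, 2L, weights, `*`)
  lam <- eigen(crossprod_projected(fit, C) / s2, symmetric = TRUE,
               only.values = TRUE)$values
  lam_max <- max(lam, 0)
  lam <- sort(lam[lam > 1e-10 * lam_max], decreasing = TRUE)
  tail <- if (length(lam) == 0L) list(p = 1, method = "fallback") else
    mixture_pvalue(Q, lam)

  structure(
    list(Q = Q, eigenvalues = lam, p_value = tail$p, p_method = tail$method,
         kernel = paste0("single:", fit$phenotype_names[k]),
         m_variants = ncol(G),
         score_components = matrix(weights * Sk, ncol = 1L,
                                   dimnames = list(geno$variant_ids,
                                                   fit$phenotype_names[k])),
         region_id = geno$region_id,
         phenotype_names = fit$phenotype_names[k]),
    class = "gei_result"
  )
}

#' @export
print.gei_result <- function(x, ...) {
  cat(sprintf("<gei_result> %s kernel, region %s: Q = %.4g, p = %.4g (%s)\n",
              x$kernel, x$region_id, x$Q, x$p_value, x$p_method))
  invisible(x)
}

#' Tidy per-variant score components of a GEI test
#'
#' @param x A `gei_result`.
#' @param ... Unused.
#' @return A tibble with one row per variant and phenotype: `variant`,
#'   `phenotype`, `score` (the weighted per-variant score).
#' @export
tidy.gei_result <- function(x, ...) {
  S <- x$score_components
  if (is.null(rownames(S))) rownames(S) <- paste0("v", seq_len(nrow(S)))
  as_tibble(S, rownames = "variant") |>
    tidyr::pivot_longer(-"variant", names_to = "phenotype",
                        values_to = "score")
}

#' One-row summary of a GEI test
#'
#' @param x A `gei_result`.
#' @param ... Unused.
#' @return A tibble: `region_id`, `kernel`, `m_variants`, `statistic`,
#'   `n_eigenvalues`, `p_value`, `p_method`.
#' @export
glance.gei_result <- function(x, ...) {
  tibble(region_id = x$region_id, kernel = x$kernel,
         m_variants = x$m_variants, statistic = x$Q,
         n_eigenvalues = length(x$eigenvalues),
         p_value = x$p_value, p_method = x$p_method)
}

#' Region-based gene-environment interaction tests
#'
#' The main user-facing driver: fits the null model once and runs the
#' requested kernel tests (and optionally the single-phenotype tests) for one
#' genotype region.
#'
#' @param geno A [genotype_region()].
#' @param pheno Data frame of n rows and K quantitative phenotypes.
#' @param covariates Data frame of covariates (intercept added if absent).
#' @param env Environmental exposure vector; it is centered here, and if no
#'   matching column exists among the covariates the centered exposure is
#'   appended so that its main effect is adjusted for in the null model.
#' @param kernels Character vector of kernels to run (default all four).
#' @param single_phenotype Also run the per-phenotype single tests?
#' @param weights Per-variant weights (default [beta_weights()]).
#' @return A tibble with one row per test: `region_id`, `chrom`, `start`,
#'   `end`, `m_variants`, `kernel`, `statistic`, `p_value`, `p_method`.
#'   The shared `gei_null_fit` and the full `gei_result` objects are attached
#'   as attributes `"fit"` and `"results"`.
#' @export
#' @examples
#' set.seed(1)
#' g <- simulate_genotypes(n = 400, seed = 7)
#' sim <- simulate_phenotypes(g, sim_config(n = 400), seed = 7)
#' gei_test(g, sim$pheno, sim$covariates, sim$env)
gei_test <- function(geno, pheno, covariates = NULL, env,
                     kernels = c("Hom", "Het", "PPK", "LPK"),
                     single_phenotype = FALSE, weights = NULL) {
  stopifnot(inherits(geno, "genotype_region"))
  n <- nrow(geno$counts)
  e <- center_environment(env)
  X <- as_covariate_matrix(covariates, n = n)
  if (!env_in_design(X, e)) {
    warn("centered environment was not among the covariates; appending it")
    X <- cbind(X, env = e)
  }
  if (is.null(weights)) weights <- beta_weights(geno$maf)
  kernels <- vapply(kernels, normalize_kernel_kind, character(1))

  fit <- fit_gei_null(pheno, X, geno, weights = weights)
  results <- purrr::map(kernels,
                        ~ gei_score_test(fit, geno, e, kernel = .x,
                                         weights = weights))
  names(results) <- kernels
  if (single_phenotype) {
    singles <- purrr::map(seq_len(fit$K),
                          ~ single_phenotype_gei_test(fit, geno, e,
                                                      phenotype = .x,
                                                      weights = weights))
    names(singles) <- paste0("single:", fit$phenotype_names)
    results <- c(results, singles)
  }

  out <- purrr::map_dfr(results, glance) |>
    dplyr::mutate(chrom = geno$chrom, start = geno$start, end = geno$end,
                  .after = "region_id")
  attr(out, "fit") <- fit
  attr(out, "results") <- results
  out
}
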