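#' Fit the no-interaction null model for one region
#'
#' Fits, for each phenotype, the linear model with covariates and fixed
#' weighted genetic main effects,
#' \deqn{y_k = X\alpha_k + GW\beta_k + \varepsilon_k,}
#' by least squares on the shared design \eqn{Z = (X, GW)}, and estimates the
#' per-phenotype residual variances and the K x K residual covariance used by
#' the multiphenotype interaction tests.
#'
#' @param pheno Data frame or matrix of n rows and K quantitative phenotypes.
#' @param covariates Data frame or matrix of covariates (an intercept column
#'   is added if absent).  The centered environmental exposure must be one of
#'   these columns so its main effect is adjusted for.
#' @param geno A [genotype_region()].
#' @param weights Per-variant weights; defaults to [beta_weights()] at the
#'   region's sample MAFs.
#'
#' @details The least-squares solve uses a rank-revealing pivoted QR, never an
#'   explicit inverse of \eqn{Z^\top Z}.  Numerically collinear weighted
#'   genotype columns are dropped from the null design (with a warning) but
#'   remain part of the interaction term under test.  Residual variances and
#'   the covariance matrix use the unbiased denominator
#'   \eqn{n - \mathrm{rank}(Z)}; the covariance is the cross-product of the
#'   per-phenotype residuals from these phenotype-specific fits.
#'
#' @return An object of class `gei_null_fit` with elements `coef`
#'   ((q+1+m) x K, zero rows for dropped columns), `mu_hat`, `resid`,
#'   `sigma2`, `Sigma_hat`, `rank`, `qr` (the pivoted QR of Z), `n`, `K`.
#' @export
fit_gei_null <- function(pheno, covariates, geno, weights = NULL) {
  stopifnot(inherits(geno, "genotype_region"))
  G <- geno$counts
  n <- nrow(G)
  y <- as_phenotype_matrix(pheno, n = n)
  X <- as_covariate_matrix(covariates, n = n)
  if (is.null(weights)) weights <- beta_weights(geno$maf)
  if (length(weights) != ncol(G)) abort("one weight per variant is required")
  if (any(weights <= 0)) abort("variant weights must be positive")

  GW <- sweep(G, 2L, weights, `*`)
  colnames(GW) <- paste0("gw_", geno$variant_ids)
  Z <- cbind(X, GW)
  fit <- stats::lm.fit(Z, y)
  rank <- fit$rank
  if (n <= rank) abort("more design columns than samples: cannot fit null model")
  if (rank < ncol(Z)) {
    dropped <- colnames(Z)[is.na(fit$coefficients[, 1L])]
    warn(paste0("dropping ", length(dropped),
                " collinear null-design column(s): ",
                paste(dropped, collapse = ", ")))
  }
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  if (is.null(dim(coef))) coef <- matrix(coef, ncol = ncol(y))
  resid <- as.matrix(fit$residuals)
  mu_hat <- y - resid
  df <- n - rank
  Sigma_hat <- crossprod(resid) / df
  Sigma_hat <- (Sigma_hat + t(Sigma_hat)) / 2
  dimnames(Sigma_hat) <- list(colnames(y), colnames(y))
  sigma2 <- diag(Sigma_hat)            # identical by construction
  names(sigma2) <- colnames(y)

  structure(
    list(coef = coef, mu_hat = mu_hat, resid = resid, sigma2 = sigma2,
         Sigma_hat = Sigma_hat, rank = rank, df_resid = df, qr = fit$qr,
         n = n, K = ncol(y), q = ncol(X) - 1L,
         phenotype_names = colnames(y), design_names = colnames(Z)),
    class = "gei_null_fit"
  )
}

#' @export
print.gei_null_fit <- function(x, ...) {
  cat(sprintf("<gei_null_fit> n = %d, K = %d phenotype(s), rank(Z) = %d\n",
              x$n, x$K, x$rank))
  cat("  residual covariance:\n")
  print(round(x$Sigma_hat, 4))
  invisible(x)
}

#' Tidy the null-model coefficients
#'
#' @param x A [fit_gei_null()] object.
#' @param ... Unused.
#' @return A tibble with one row per design column and phenotype:
#'   `phenotype`, `term`, `estimate`.
#' @export
tidy.gei_null_fit <- function(x, ...) {
  co <- x$coef
  rownames(co) <- x$design_names
  as_tibble(co, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "phenotype",
                        values_to = "estimate") |>
    dplyr::arrange(.data$phenotype)
}

#' One-row summary of the null-model fit
#'
#' @param x A [fit_gei_null()] object.
#' @param ... Unused.
#' @return A tibble with `n`, `K`, `rank_z`, `df_resid` and per-phenotype
#'   residual variances spread into `sigma2_*` columns.
#' @export
glance.gei_null_fit <- function(x, ...) {
  s2 <- as.list(x$sigma2)
  names(s2) <- paste0("sigma2_", names(s2))
  dplyr::bind_cols(
    tibble(n = x$n, K = x$K, rank_z = x$rank, df_resid = x$df_resid),
    as_tibble(s2)
  )
}

# C^T P C without forming the n x n projector P = I - Z (Z^T Z)^- Z^T:
# uses the rank-revealing QR of Z kept in the fit.
crossprod_projected <- function(fit, C) {
  CtC <- crossprod(C)
  QtC <- qr.qty(fit$qr, C)[seq_len(fit$rank), , drop = FALSE]
  out <- CtC - crossprod(QtC)
  (out + t(out)) / 2
}
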