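#' Phenotype-space kernels
#'
#' Builds the K x K kernel \eqn{\Sigma_P} that models the correlation among a
#' variant's interaction effects across phenotypes:
#' \describe{
#'   \item{Hom}{homogeneous effects, \eqn{\Sigma_P = 1_K 1_K^\top} (all-ones);}
#'   \item{Het}{heterogeneous (independent) effects, \eqn{\Sigma_P = I_K};}
#'   \item{PPK}{projection phenotype kernel, the estimated phenotype
#'     covariance \eqn{\hat\Sigma};}
#'   \item{LPK}{linear phenotype kernel, its square \eqn{\hat\Sigma^2}.}
#' }
#'
#' @param kind One of `"Hom"`, `"Het"`, `"PPK"`, `"LPK"` (case-insensitive).
#' @param Sigma_hat Estimated K x K phenotype covariance (required for PPK and
#'   LPK); must be symmetric positive semi-definite.
#' @param K Number of phenotypes (taken from `Sigma_hat` when supplied).
#' @return A symmetric positive semi-definite K x K matrix.
#' @export
#' @examples
#' build_kernel("Hom", K = 3)
#' build_kernel("LPK", Sigma_hat = matrix(c(1, .5, .5, 1), 2))
build_kernel <- function(kind, Sigma_hat = NULL, K = NULL) {
  kind <- normalize_kernel_kind(kind)
  if (is.null(K)) {
    if (is.null(Sigma_hat)) abort("supply K or Sigma_hat")
    K <- nrow(Sigma_hat)
  }
  if (kind %in% c("PPK", "LPK")) {
    if (is.null(Sigma_hat)) abort(paste0(kind, " kernel needs Sigma_hat"))
    check_psd(Sigma_hat, "Sigma_hat")
  }
  switch(kind,
    Hom = matrix(1, K, K),
    Het = diag(K),
    PPK = Sigma_hat,
    LPK = Sigma_hat %*% Sigma_hat
  )
}

kernel_kinds <- c("Hom", "Het", "PPK", "LPK")

normalize_kernel_kind <- function(kind) {
  hit <- match(tolower(kind), tolower(kernel_kinds))
  if (anyNA(hit)) {
    abort(sprintf("unknown kernel '%s'; choose from %s", kind,
                  paste(kernel_kinds, collapse = ", ")))
  }
  kernel_kinds[hit]
}

check_psd <- function(M, label, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1e-300)) {
    abort(sprintf("%s is not positive semi-definite", label))
  }
  invisible(ev)
}

# symmetric PSD square root; negative eigenvalues are clipped at zero
sym_sqrt <- function(M, tol = 1e-8) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  vals <- eg$values
  vals[vals < tol * max(abs(vals), 1e-300)] <- 0
  eg$vectors %*% (sqrt(vals) * t(eg$vectors))
}
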