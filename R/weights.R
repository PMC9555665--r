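#' Beta(1, 25) rare-variant weights
#'
#' Computes the standard rare-variant weight for each variant: the density of
#' the Beta(1, 25) distribution evaluated at the minor allele frequency,
#' \eqn{w_j = 25 (1 - \mathrm{MAF}_j)^{24}}.  Rarer variants receive larger
#' weights; the weight is strictly decreasing in MAF.
#'
#' @param maf Numeric vector of minor allele frequencies, each in (0, 0.5].
#' @param shape1,shape2 Beta shape parameters; the default (1, 25) is the
#'   convention used throughout rare-variant kernel tests.
#' @return Numeric vector of positive weights, one per variant.
#' @export
#' @examples
#' beta_weights(c(0.001, 0.01, 0.05))
beta_weights <- function(maf, shape1 = 1, shape2 = 25) {
  maf <- as.numeric(maf)
  if (length(maf) == 0L) abort("need at least one frequency")
  if (anyNA(maf) || any(!is.finite(maf))) abort("frequencies must be finite")
  if (any(maf <= 0) || any(maf > 0.5)) {
    abort("minor allele frequencies must lie in (0, 0.5]")
  }
  dbeta(maf, shape1, shape2)
}
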