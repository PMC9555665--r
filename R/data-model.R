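#' Region-grouped rare-variant genotypes
#'
#' A `genotype_region` bundles the minor-allele count matrix of one gene or
#' genomic region with per-variant metadata.  Counts are coded 0/1/2 copies of
#' the minor allele, where "minor" is defined within the analysed samples:
#' each variant's sample allele frequency is at most 0.5.
#'
#' @param counts Integer-valued n x m matrix of minor-allele counts in
#'   \{0, 1, 2\}; no missing values (impute or filter upstream).
#' @param variant_ids Character vector of m variant labels.
#' @param positions Integer vector of m 1-based positions.
#' @param region_id Label for the region (e.g. a gene symbol).
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive region bounds.
#'
#' @details The minor allele frequency stored in `$maf` is always recomputed
#'   from `counts` on the analysed samples (never taken from VCF INFO fields),
#'   so that weights and filters are reproducible on arbitrary sample subsets.
#'
#' @return An object of class `genotype_region` with fields `counts`,
#'   `variant_ids`, `positions`, `maf`, `region_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' g <- genotype_region(matrix(c(0, 1, 0, 0, 0, 1), nrow = 3),
#'                      variant_ids = c("v1", "v2"), positions = c(11L, 25L),
#'                      region_id = "toy", chrom = "1", start = 1L, end = 100L)
#' g$maf
genotype_region <- function(counts, variant_ids = NULL, positions = NULL,
                            region_id = "region", chrom = "1",
                            start = 1L, end = NA_integer_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  m <- ncol(counts)
  if (m < 1L) abort("a genotype region needs at least one variant")
  if (anyNA(counts)) abort("genotype counts must not contain missing values")
  if (!all(counts %in% c(0, 1, 2))) {
    abort("genotype counts must be minor-allele copies in {0, 1, 2}")
  }
  cs <- colSums(counts)
  if (any(cs == 0)) abort("monomorphic (all-zero) variant columns are not allowed")
  maf <- colMeans(counts) / 2
  if (any(maf > 0.5)) {
    abort("some columns encode the major allele; flip counts so frequencies are <= 0.5")
  }
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(m))
  if (is.null(positions)) positions <- seq_len(m)
  stopifnot(length(variant_ids) == m, length(positions) == m)
  structure(
    list(counts = counts, variant_ids = as.character(variant_ids),
         positions = as.integer(positions), maf = maf,
         region_id = region_id, chrom = as.character(chrom),
         start = as.integer(start), end = as.integer(end)),
    class = "genotype_region"
  )
}

#' @export
print.genotype_region <- function(x, ...) {
  cat(sprintf("<genotype_region> %s (%s:%s-%s)\n", x$region_id, x$chrom,
              x$start, x$end))
  cat(sprintf("  %d samples x %d variants, MAF in [%.3g, %.3g]\n",
              nrow(x$counts), ncol(x$counts), min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_region <- function(x) dim(x$counts)

#' Tidy per-variant metadata of a genotype region
#'
#' @param x A [genotype_region()].
#' @param ... Unused.
#' @return A tibble with one row per variant: `variant_id`, `position`,
#'   `maf`, `n_carriers`.
#' @export
tidy.genotype_region <- function(x, ...) {
  tibble(
    variant_id = x$variant_ids,
    position = x$positions,
    maf = x$maf,
    n_carriers = colSums(x$counts > 0)
  )
}

# ---- internal coercion helpers shared by the model-fitting layer ----------

# n x K numeric phenotype matrix from a data frame / matrix / vector
as_phenotype_matrix <- function(y, n = NULL) {
  y <- as.matrix(as.data.frame(y))
  storage.mode(y) <- "double"
  if (anyNA(y)) abort("phenotypes must not contain missing values")
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  if (!is.null(n) && nrow(y) != n) {
    abort(sprintf("phenotype rows (%d) do not match sample count (%d)",
                  nrow(y), n))
  }
  y
}

# design matrix with a leading intercept column; covariates may be NULL
as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("covariates must not contain missing values")
  if (nrow(X) != n) abort("covariate rows do not match sample count")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  has_intercept <- ncol(X) >= 1L && all(X[, 1L] == 1)
  if (!has_intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  X
}

#' Center an environmental exposure
#'
#' The environmental main effect must be adjusted for in the null model, so
#' the exposure is mean-centered and expected to appear as a covariate column.
#'
#' @param e Numeric vector of exposures, one per sample.
#' @return The centered vector (mean zero).
#' @export
center_environment <- function(e) {
  e <- as.numeric(e)
  if (anyNA(e)) abort("environmental exposures must not contain missing values")
  e <- e - mean(e)
  if (sd(e) > 0 && abs(mean(e)) >= 1e-8 * sd(e)) {
    abort("environment centering failed")  # unreachable guard
  }
  e
}

# TRUE if some column of X equals e (up to numeric noise)
env_in_design <- function(X, e, tol = 1e-8) {
  scale <- max(sd(e), 1e-12)
  any(apply(X, 2L, function(col) max(abs(col - e)) < tol * scale))
}
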