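#' Empirical power study
#'
#' Repeats the full pipeline — fresh rare-variant genotypes, fresh phenotypes
#' under the alternative model, null fit and kernel tests — and tabulates the
#' fraction of replicates significant at `alpha` for each kernel, with
#' Monte-Carlo standard errors \eqn{\sqrt{\hat p(1-\hat p)/R}}.
#'
#' Replicate r runs on substreams derived from `seed + r`, so partial runs
#' are reproducible and extensions resume deterministically.
#'
#' @param cfg A [sim_config()] describing the alternative scenario.
#' @param alpha Significance level (e.g. 2.5e-6 for a genome-wide study of
#'   20,000 genes, or 0.05 nominal).
#' @param n_replicates Number of replicates.
#' @param kernels Kernels to evaluate.
#' @param seed Integer master seed.
#' @return A tibble of class `gei_power` with one row per kernel: `kernel`,
#'   `alpha`, `n_replicates`, `n_significant`, `power`, `mc_se`.  The full
#'   per-replicate p-values are attached as attribute `"replicates"`
#'   (tibble: `replicate`, `kernel`, `p_value`).
#' @export
run_power_study <- function(cfg, alpha = 2.5e-6, n_replicates = 300,
                            kernels = c("Hom", "Het", "PPK", "LPK"),
                            seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  kernels <- vapply(kernels, normalize_kernel_kind, character(1))
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    p <- replicate_pvalues(cfg, alternative = TRUE, kernels = kernels,
                           seed = seed + r)
    tibble(replicate = r, kernel = names(p), p_value = unname(p))
  })
  out <- reps |>
    dplyr::group_by(.data$kernel) |>
    dplyr::summarise(
      alpha = alpha,
      n_replicates = dplyr::n(),
      n_significant = sum(.data$p_value < alpha),
      power = .data$n_significant / .data$n_replicates,
      mc_se = sqrt(.data$power * (1 - .data$power) / .data$n_replicates),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$kernel, kernels))
  attr(out, "replicates") <- reps
  class(out) <- c("gei_power", class(out))
  out
}

#' Null-distribution (QQ) study
#'
#' Simulates phenotypes under the null model — several phenotype/covariate
#' replicates per genotype replicate — runs the kernel tests, and returns the
#' pooled p-values paired with their expected uniform quantiles for
#' quantile-quantile inspection.
#'
#' @param cfg A [sim_config()] (its `gamma_sd`/`l` are irrelevant under the
#'   null).
#' @param n_genotype_replicates Genotype datasets to draw.
#' @param pheno_reps_per_genotype Phenotype/covariate replicates per genotype
#'   dataset.
#' @param kernels Kernels to evaluate.
#' @param seed Integer master seed.
#' @return A tibble of class `gei_qq`: `kernel`, `replicate`, `p_value`,
#'   `expected` (uniform plotting position), `observed_nlog10`,
#'   `expected_nlog10`.
#' @export
run_null_study <- function(cfg, n_genotype_replicates = 25,
                           pheno_reps_per_genotype = 20,
                           kernels = c("Hom", "Het", "PPK", "LPK"),
                           seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  kernels <- vapply(kernels, normalize_kernel_kind, character(1))
  grid <- tidyr::expand_grid(g = seq_len(n_genotype_replicates),
                             r = seq_len(pheno_reps_per_genotype))
  reps <- purrr::pmap_dfr(grid, function(g, r) {
    geno <- simulate_genotypes(cfg$n, cfg$region_bp, cfg$rare_maf_max,
                               cfg$variant_density,
                               seed = substream_seed(seed + g, "genotypes"))
    p <- replicate_pvalues(cfg, alternative = FALSE, kernels = kernels,
                           seed = seed + g * 100003 + r, geno = geno)
    tibble(genotype = g, replicate = r, kernel = names(p),
           p_value = unname(p))
  })
  out <- reps |>
    dplyr::group_by(.data$kernel) |>
    dplyr::arrange(.data$p_value, .by_group = TRUE) |>
    dplyr::mutate(expected = (seq_along(.data$p_value) - 0.5) /
                    dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(observed_nlog10 = -log10(.data$p_value),
                  expected_nlog10 = -log10(.data$expected))
  class(out) <- c("gei_qq", class(out))
  out
}

# one simulated replicate -> named p-values per kernel
replicate_pvalues <- function(cfg, alternative, kernels, seed,
                              geno = NULL) {
  if (is.null(geno)) {
    geno <- simulate_genotypes(cfg$n, cfg$region_bp, cfg$rare_maf_max,
                               cfg$variant_density,
                               seed = substream_seed(seed, "genotypes"))
  }
  sim <- simulate_phenotypes(geno, cfg, alternative = alternative,
                             seed = substream_seed(seed, "phenotypes"))
  fit <- fit_gei_null(sim$pheno, sim$covariates, geno)
  vapply(kernels, function(k) {
    gei_score_test(fit, geno, sim$env, kernel = k)$p_value
  }, numeric(1))
}

#' Plot an empirical power table
#'
#' @param object A [run_power_study()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of power per kernel with 1-SE error bars.
#' @export
autoplot.gei_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$kernel, y = .data$power)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$power - .data$mc_se, 0),
                                        ymax = pmin(.data$power + .data$mc_se, 1)),
                           width = 0.2) +
    ggplot2::labs(x = "kernel", y = "empirical power") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of null p-values
#'
#' @param object A [run_null_study()] result.
#' @param ... Unused.
#' @return A ggplot QQ panel (one facet per kernel) of observed vs expected
#'   -log10 p-values with the identity reference line.
#' @export
autoplot.gei_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected_nlog10,
                                       y = .data$observed_nlog10)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~kernel) +
    ggplot2::labs(x = expression(-log[10] * " expected p"),
                  y = expression(-log[10] * " observed p")) +
    ggplot2::theme_minimal()
}
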