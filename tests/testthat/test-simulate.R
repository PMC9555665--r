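test_that("genotype generator is deterministic and well formed", {
  g1 <- simulate_genotypes(500, seed = 5)
  g2 <- simulate_genotypes(500, seed = 5)
  expect_identical(g1$counts, g2$counts)
  expect_true(all(g1$counts %in% c(0, 1, 2)))
  expect_true(all(colSums(g1$counts) > 0))
  expect_equal(g1$maf, colMeans(g1$counts) / 2)
  g3 <- simulate_genotypes(500, seed = 6)
  expect_false(identical(g1$counts, g3$counts))
})

test_that("realised MAFs respect the rare threshold up to sampling slack", {
  mafs <- unlist(lapply(1:40, function(r)
    simulate_genotypes(2000, seed = 100 + r)$maf))
  # population MAFs are truncated at 0.01; binomial sampling at n=2000 adds
  # at most a few s.e. (~sqrt(0.01/4000) ~ 0.0016) of slack
  expect_lt(max(mafs), 0.01 + 5 * sqrt(0.01 / 4000))
  m_counts <- vapply(1:40, function(r)
    ncol(simulate_genotypes(2000, seed = 100 + r)$counts), numeric(1))
  expect_equal(mean(m_counts), 30, tolerance = 0.12)
})

test_that("configuration is validated", {
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(l = c(1, 2, 0, 0)), "binary")
  cfg <- sim_config(K = 2, l = c(1, 0), sex_coef = 0.1, beta_main = 0.2)
  expect_length(cfg$beta_main, 2L)
})

test_that("causal count rounds theta * m with a floor of one", {
  g <- simulate_genotypes(1000, seed = 9)
  m <- ncol(g$counts)
  sim <- simulate_phenotypes(g, sim_config(n = 1000, theta = 0.2), seed = 2)
  expect_length(sim$causal, max(1L, round(0.2 * m)))
  sim_tiny <- simulate_phenotypes(g, sim_config(n = 1000, theta = 1e-4),
                                  seed = 2)
  expect_length(sim_tiny$causal, 1L)
})

test_that("degenerate alternative replays the null stream exactly", {
  g <- simulate_genotypes(800, seed = 14)
  cfg0 <- sim_config(n = 800, gamma_sd = 0)
  s_null <- simulate_phenotypes(g, cfg0, alternative = FALSE, seed = 77)
  s_alt <- simulate_phenotypes(g, cfg0, alternative = TRUE, seed = 77)
  expect_identical(s_null$pheno, s_alt$pheno)
  expect_identical(s_null$covariates, s_alt$covariates)
})

test_that("error correlations and variances match the generative covariance", {
  cfg <- sim_config(n = 4000, rho = 0.25)
  g <- simulate_genotypes(4000, seed = 41)
  sim <- simulate_phenotypes(g, cfg, alternative = FALSE, seed = 41)
  fit <- fit_gei_null(sim$pheno, sim$covariates, g)
  R <- stats::cov2cor(fit$Sigma_hat)
  expect_true(all(abs(R[upper.tri(R)] - 0.25) < 0.05))
  Sigma_gen <- sim_error_covariance(cfg)
  expect_equal(Sigma_gen[1, 1], 4)
  expect_equal(Sigma_gen[1, 2], 0.25 * 2)
  expect_equal(Sigma_gen[2, 3], 0.25)
})

test_that("interaction effects are confined to flagged phenotypes", {
  g <- simulate_genotypes(600, seed = 55)
  cfg <- sim_config(n = 600, l = c(1, 0, 0, 0), gamma_sd = 0.5)
  sim <- simulate_phenotypes(g, cfg, alternative = TRUE, seed = 55)
  cfg_null <- sim_config(n = 600, l = c(1, 0, 0, 0), gamma_sd = 0)
  sim0 <- simulate_phenotypes(g, cfg_null, alternative = TRUE, seed = 55)
  delta <- as.matrix(sim$pheno) - as.matrix(sim0$pheno)
  expect_gt(max(abs(delta[, 1])), 0)
  expect_equal(max(abs(delta[, 2:4])), 0)
})
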