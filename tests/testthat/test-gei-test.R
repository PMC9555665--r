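test_that("trace form matches brute-force Kronecker materialisation", {
  for (seed in 1:4) {
    inst <- random_instance(n = 15, m = 3, K = 2, seed = seed)
    fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
    for (kern in c("Hom", "Het", "PPK", "LPK")) {
      Sigma_P <- build_kernel(kern, Sigma_hat = fit$Sigma_hat)
      res <- gei_score_test(fit, inst$geno, inst$e, kernel = kern,
                            weights = inst$w)
      Q_ref <- brute_force_Q(fit, inst$geno, inst$w, inst$e, Sigma_P)
      expect_equal(res$Q, Q_ref, tolerance = 1e-10)
    }
  }
})

test_that("eigenvalue spectrum matches the materialised Kronecker matrix", {
  inst <- random_instance(n = 12, m = 3, K = 2, seed = 9)
  fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  Z <- cbind(inst$X, sweep(inst$geno$counts, 2, inst$w, `*`))
  for (kern in c("Het", "PPK")) {
    Sigma_P <- build_kernel(kern, Sigma_hat = fit$Sigma_hat)
    res <- gei_score_test(fit, inst$geno, inst$e, kernel = kern,
                          weights = inst$w)
    ref <- brute_force_psi_eigen(fit, inst$geno, inst$w, inst$e, Sigma_P, Z)
    ref <- ref[ref > 1e-10 * max(ref)]
    expect_equal(res$eigenvalues, ref, tolerance = 1e-8)
  }
})

test_that("heterogeneous kernel at K = 1 reduces to the single-phenotype test", {
  inst <- random_instance(n = 30, m = 4, K = 1, seed = 13)
  fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  multi <- gei_score_test(fit, inst$geno, inst$e, kernel = "Het",
                          weights = inst$w)
  single <- single_phenotype_gei_test(fit, inst$geno, inst$e, phenotype = 1,
                                      weights = inst$w)
  expect_equal(multi$Q, single$Q, tolerance = 1e-10)
  expect_equal(multi$eigenvalues, single$eigenvalues, tolerance = 1e-10)
  expect_equal(multi$p_value, single$p_value, tolerance = 1e-10)

  # closed form: Q = sigma^-4 * sum_j w_j^2 (sum_i E_i G_ij r_i)^2
  s2 <- fit$sigma2[[1]]
  Sj <- as.vector(crossprod(inst$geno$counts * inst$e, fit$resid[, 1]))
  expect_equal(single$Q, sum(inst$w^2 * Sj^2) / s2^2, tolerance = 1e-10)
})

test_that("linear phenotype kernel decomposes into single-phenotype pieces", {
  inst <- random_instance(n = 40, m = 4, K = 3, seed = 17)
  fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  res <- gei_score_test(fit, inst$geno, inst$e, kernel = "LPK",
                        weights = inst$w)
  # with Sigma_P = Sigma^2 the phenotype-space matrix is exactly I_K, so
  # Q is the unscaled sum over phenotypes of sum_j w_j^2 (E G r_k)_j^2
  S <- inst$w * crossprod(inst$geno$counts * inst$e, fit$resid)
  expect_equal(res$Q, sum(S^2), tolerance = 1e-10)
})

test_that("Q and spectrum scale as c^2 in the weights, p unchanged", {
  inst <- random_instance(n = 30, m = 3, K = 2, seed = 19)
  c0 <- 3.7
  fit1 <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  fit2 <- fit_gei_null(inst$y, inst$X, inst$geno, weights = c0 * inst$w)
  r1 <- gei_score_test(fit1, inst$geno, inst$e, "PPK", weights = inst$w)
  r2 <- gei_score_test(fit2, inst$geno, inst$e, "PPK", weights = c0 * inst$w)
  expect_equal(r2$Q, c0^2 * r1$Q, tolerance = 1e-10)
  expect_equal(r2$eigenvalues, c0^2 * r1$eigenvalues, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("Q is invariant to sample and variant reordering", {
  inst <- random_instance(n = 25, m = 4, K = 2, seed = 23)
  fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  base <- gei_score_test(fit, inst$geno, inst$e, "Het", weights = inst$w)

  ip <- sample(25)
  geno_p <- genotype_region(inst$geno$counts[ip, ])
  fit_p <- fit_gei_null(inst$y[ip, , drop = FALSE], inst$X[ip, ], geno_p,
                        weights = inst$w)
  perm <- gei_score_test(fit_p, geno_p, inst$e[ip], "Het", weights = inst$w)
  expect_equal(perm$Q, base$Q, tolerance = 1e-10)
  expect_equal(perm$p_value, base$p_value, tolerance = 1e-9)

  jp <- c(3, 1, 4, 2)
  geno_v <- genotype_region(inst$geno$counts[, jp])
  fit_v <- fit_gei_null(inst$y, inst$X, geno_v, weights = inst$w[jp])
  perm_v <- gei_score_test(fit_v, geno_v, inst$e, "Het", weights = inst$w[jp])
  expect_equal(perm_v$Q, base$Q, tolerance = 1e-10)
})

test_that("single-variant region gives a one-term mixture", {
  inst <- random_instance(n = 40, m = 1, K = 1, seed = 29)
  fit <- fit_gei_null(inst$y, inst$X, inst$geno, weights = inst$w)
  res <- single_phenotype_gei_test(fit, inst$geno, inst$e, weights = inst$w)
  expect_length(res$eigenvalues, 1L)
  p_exact <- stats::pchisq(res$Q / res$eigenvalues, df = 1, lower.tail = FALSE)
  expect_equal(res$p_value, p_exact, tolerance = 1e-3)
})

test_that("sum of eigenvalues tracks the null mean of Q", {
  cfg <- sim_config(n = 300, K = 2, sex_coef = c(0.1, 0.5),
                    beta_main = c(0.1, 0.2), l = c(1, 1))
  diffs <- replicate(150, {
    r <- sample.int(1e6, 1)
    g <- simulate_genotypes(300, seed = r)
    sim <- simulate_phenotypes(g, cfg, alternative = FALSE, seed = r)
    # rare duplicated ultra-rare variant columns at n = 300 warn on dropping
    fit <- suppressWarnings(fit_gei_null(sim$pheno, sim$covariates, g))
    res <- gei_score_test(fit, g, sim$env, "Het")
    res$Q - sum(res$eigenvalues)
  })
  scale <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * scale)
})

test_that("gei_test orchestrates kernels and reuses one fit", {
  set.seed(31)
  g <- simulate_genotypes(400, seed = 33)
  cfg <- sim_config(n = 400)
  sim <- simulate_phenotypes(g, cfg, seed = 33)
  res <- gei_test(g, sim$pheno, sim$covariates, sim$env,
                  kernels = c("het", "ppk"))
  expect_equal(nrow(res), 2L)
  expect_equal(res$kernel, c("Het", "PPK"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_s3_class(attr(res, "fit"), "gei_null_fit")
  expect_error(gei_test(g, sim$pheno, sim$covariates, sim$env,
                        kernels = "fancy"), "unknown kernel")

  # per-phenotype single tests ride along on the same fit
  res_s <- gei_test(g, sim$pheno, sim$covariates, sim$env, kernels = "Het",
                    single_phenotype = TRUE)
  expect_equal(nrow(res_s), 1L + cfg$K)
  expect_true(all(grepl("^single:", res_s$kernel[-1])))
})

test_that("an environment missing from the covariates is appended with a warning", {
  set.seed(35)
  g <- simulate_genotypes(300, seed = 35)
  sim <- simulate_phenotypes(g, sim_config(n = 300), seed = 35)
  no_env <- sim$covariates[, c("sex", "age")]
  expect_warning(
    res <- gei_test(g, sim$pheno, no_env, sim$env, kernels = "Het"),
    "appending"
  )
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
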