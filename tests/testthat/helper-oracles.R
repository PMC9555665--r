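# Independent brute-force oracles for the score statistic and its spectrum,
# materialising the full Kronecker forms that the implementation avoids.

# small random valid dataset: genotypes, phenotypes, covariates incl. the
# centered environment, and matching weights
random_instance <- function(n = 12, m = 3, K = 2, seed = 1) {
  set.seed(seed)
  repeat {
    G <- matrix(rbinom(n * m, 2L, 0.2), n, m)
    maf <- colMeans(G) / 2
    if (all(colSums(G) > 0) && all(maf <= 0.5)) break
  }
  e <- rnorm(n)
  e <- e - mean(e)
  X <- cbind(1, rnorm(n), e)
  colnames(X) <- c("(Intercept)", "x1", "env")
  y <- matrix(rnorm(n * K), n, K)
  colnames(y) <- paste0("y", seq_len(K))
  w <- beta_weights(pmin(maf, 0.5))
  geno <- genotype_region(G, region_id = "toy")
  list(geno = geno, y = y, X = X, e = e, w = w)
}

# Q by direct materialisation of the nK x nK Kronecker quadratic form
brute_force_Q <- function(fit, geno, w, e, Sigma_P) {
  B <- diag(e) %*% geno$counts %*% diag(w, length(w))
  B <- B %*% t(B)                                   # EGWWG^T E
  Si <- solve(fit$Sigma_hat)
  M <- kronecker(Si %*% Sigma_P %*% Si, B)
  r <- as.vector(fit$resid)                         # vec(y - mu), columns stacked
  drop(t(r) %*% M %*% r)
}

# eigenvalues by direct eigendecomposition of the materialised mK x mK matrix
brute_force_psi_eigen <- function(fit, geno, w, e, Sigma_P, Z) {
  n <- nrow(Z)
  P <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z) # Z full rank in fixtures
  C <- diag(e) %*% geno$counts %*% diag(w, length(w))
  eg <- eigen((Sigma_P + t(Sigma_P)) / 2, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Psi <- kronecker(root %*% solve(fit$Sigma_hat) %*% root, t(C) %*% P %*% C)
  sort(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Monte-Carlo tail estimate for sum(lambda * chisq_1), with its standard error
mc_mixture_tail <- function(q, lambda, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  acc <- numeric(n_draws)
  for (lam in lambda) acc <- acc + lam * stats::rchisq(n_draws, df = 1)
  p <- mean(acc > q)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}
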