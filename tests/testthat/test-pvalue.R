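test_that("degenerate equal-weight mixtures give exact chi-square tails", {
  # single unit weight: the mixture IS chi-square(1)
  for (p_true in c(0.5, 0.05, 1e-4, 1e-8)) {
    q <- stats::qchisq(p_true, df = 1, lower.tail = FALSE)
    res <- mixture_pvalue(q, 1)
    expect_equal(res$method, "exact")
    expect_equal(res$p, p_true, tolerance = 1e-10)
  }
  # three unit weights: chi-square(3); scaling shared by all weights too
  for (p_true in c(0.5, 0.05, 1e-6)) {
    q <- stats::qchisq(p_true, df = 3, lower.tail = FALSE)
    expect_equal(mixture_pvalue(q, c(1, 1, 1))$p, p_true, tolerance = 1e-10)
    expect_equal(mixture_pvalue(2.5 * q, c(2.5, 2.5, 2.5))$p, p_true,
                 tolerance = 1e-10)
  }
})

test_that("saddlepoint approximates unequal-weight chi-square combinations", {
  # spectra close to (but not exactly) chi-square exercise the general path;
  # first-order saddlepoint accuracy on few-term mixtures is a few percent
  eps <- 1e-4
  for (df in c(3, 10)) {
    lambda <- 1 + eps * seq_len(df)
    for (p_true in c(0.05, 1e-3, 1e-6)) {
      q <- stats::qchisq(p_true, df = df, lower.tail = FALSE) * mean(lambda)
      res <- mixture_pvalue(q, lambda)
      expect_equal(res$method, "saddlepoint")
      expect_equal(res$p, p_true, tolerance = 0.05)
    }
  }
})

test_that("moment-matching fallback is close to the exact chi-square tail", {
  q <- stats::qchisq(0.05, df = 1, lower.tail = FALSE)
  expect_equal(mixture_pvalue(q, 1, method = "liu")$p, 0.05, tolerance = 0.01)
  expect_equal(mixture_pvalue(0, c(1, 2))$p, 1)
})

test_that("saddlepoint and fallback agree on random spectra", {
  set.seed(42)
  for (i in 1:10) {
    lambda <- rexp(sample(3:40, 1))
    total <- sum(lambda)
    for (q in total * c(1.5, 3, 6)) {
      ps <- mixture_pvalue(q, lambda, method = "saddlepoint")$p
      pl <- mixture_pvalue(q, lambda, method = "liu")$p
      if (ps >= 1e-6 && ps <= 0.5) {
        expect_equal(pl, ps, tolerance = 0.1)
      }
    }
  }
})

test_that("tail probability is scale invariant and monotone in q", {
  lambda <- c(2, 0.5, 0.1)
  p1 <- mixture_pvalue(3.7, lambda)$p
  p2 <- mixture_pvalue(3.7 * 1e3, lambda * 1e3)$p
  expect_equal(p1, p2, tolerance = 1e-10)
  qs <- seq(0.2, 30, length.out = 40)
  ps <- vapply(qs, function(q) mixture_pvalue(q, lambda)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  # p -> 1 as q -> 0+
  expect_gt(mixture_pvalue(1e-8, lambda)$p, 0.999)
})

test_that("left-tail saddlepoints (p near 1) are handled", {
  lambda <- rexp(20)
  p <- mixture_pvalue(0.05 * sum(lambda), lambda)
  expect_equal(p$method, "saddlepoint")
  expect_gt(p$p, 0.99)
})

test_that("extreme statistics do not underflow to zero", {
  res <- mixture_pvalue(1e6, c(1, 0.5))
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
})

test_that("near-mean statistics are perturbed, not singular", {
  lambda <- c(1, 2, 3)
  p <- mixture_pvalue(sum(lambda) * (1 + 1e-6), lambda)
  expect_true(is.finite(p$p))
  expect_true(p$p > 0.2 && p$p < 0.8)
})
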