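test_that("partial-sum covariance equals the min(Hi,Hj) - HiHj closed form", {
  withr::with_seed(21, {
    for (i in 1:10) {
      theta <- runif(1, 0.05, 0.95)
      k <- sample(2:10, 1)
      H <- geom1_cdf(theta, k)
      closed <- outer(H, H, pmin) - tcrossprod(H)
      expect_equal(covariance_known(theta, k), closed, tolerance = 1e-12)
    }
  })
  expect_equal(covariance_known(0.5, 2)[1, 2], 0.125)
  k <- 6
  H <- geom1_cdf(0.3, k)
  expect_equal(diag(covariance_known(0.3, k)), H * (1 - H))
})

test_that("MLE correction denominator converges to the Fisher information", {
  for (theta in c(0.1, 0.5, 0.9)) {
    btDb <- function(k) {
      sum(geom1_score(theta, k)^2 / geom1_pmf(theta, k))
    }
    # deepest k at which the pmf is still representable (no denormal 0/0)
    k <- floor(-300 / log10(1 - theta))
    expect_equal(btDb(k), 1 / (theta^2 * (1 - theta)), tolerance = 1e-6)
  }
})

test_that("estimated-theta covariance is a strict PSD shrinkage of the known case", {
  for (theta in c(0.2, 0.5, 0.8)) {
    k <- 30
    known <- covariance_known(theta, k)
    est <- covariance_estimated(theta, k)
    expect_lt(sum(diag(est)), sum(diag(known)))
    diffm <- known - est
    ev <- eigen((diffm + t(diffm)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})

test_that("weight matrix is the pmf (W2) or variance-standardised pmf (A2)", {
  expect_equal(diag(weight_matrix("w2", 0.5, 4)), geom1_pmf(0.5, 4))
  expect_equal(weight_matrix("a2", 0.5, 1)[1, 1], 2)
  V <- weight_matrix("a2", 0.3, 8)
  expect_true(all(diag(V) > 0))
  expect_equal(V[lower.tri(V)], rep(0, sum(lower.tri(V))))
})

test_that("eigen spectrum is non-negative, trace-preserving, and rank-deficient in estimated mode", {
  for (theta in c(0.1, 0.5, 0.9)) {
    for (st in c("w2", "a2")) {
      k <- max(ceiling(log(1e-10) / log1p(-theta)), 5L)
      sp <- eigen_spectrum(st, theta, estimated = TRUE, k = k)
      expect_true(all(sp$lambdas >= 0))
      # eigenvalue sum matches the trace; clipping removes a negligible share
      expect_equal(sp$sum_raw, sp$trace, tolerance = 1e-8)
      expect_lt(abs(sum(sp$lambdas) - sp$trace), 1e-6 * sp$trace)
      # trace identity: sum lambda = sum V_ii Sigma_ii
      Sig <- covariance_estimated(theta, k)
      expect_equal(sp$trace, sum(diag(weight_matrix(st, theta, k)) * diag(Sig)))
      # one-parameter correction removes at least one degree of freedom
      expect_lte(min(eigen_spectrum(st, theta, TRUE, k)$lambdas),
                 1e-6 * max(sp$lambdas))
    }
  }
})

test_that("known-theta Anderson-Darling eigenvalue sum converges to 1", {
  for (theta in c(0.2, 0.5, 0.8)) {
    k <- ceiling(log(1e-12) / log1p(-theta))
    sp <- eigen_spectrum("a2", theta, estimated = FALSE, k = k)
    # trace = sum p_i exactly, and the truncated mass tends to 1
    expect_equal(sum(sp$lambdas), 1 - (1 - theta)^k, tolerance = 1e-8)
    expect_equal(sum(sp$lambdas), 1, tolerance = 1e-6)
  }
})

test_that("truncation rule enforces the residual-mass floor and converges", {
  k <- choose_truncation("w2", 0.5, estimated = TRUE, alpha = 0.05)
  expect_gte(k, ceiling(log(1e-10) / log1p(-0.5)))  # >= 34
  expect_lt((1 - 0.5)^k, 1e-10)
  k_small <- choose_truncation("a2", 0.05, estimated = TRUE, alpha = 0.05)
  expect_gte(k_small, 449)
  # quantile is stable beyond the chosen k
  sp1 <- eigen_spectrum("w2", 0.5, TRUE, k)
  sp2 <- eigen_spectrum("w2", 0.5, TRUE, 2 * k)
  expect_equal(wchi2_quantile(sp1, 0.05), wchi2_quantile(sp2, 0.05),
               tolerance = 5e-5)
})
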