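test_that("pmf, cdf and survival vectors follow the closed forms", {
  expect_equal(geom1_pmf(0.5, 1), 0.5)
  expect_equal(geom1_pmf(0.5, 3), c(0.5, 0.25, 0.125))
  expect_equal(geom1_pmf(0.512, 2), c(0.512, 0.249856))
  expect_equal(geom1_cdf(0.5, 4), c(0.5, 0.75, 0.875, 0.9375))

  for (theta in c(0.05, 0.3, 0.77)) {
    k <- 40
    p <- geom1_pmf(theta, k)
    expect_true(all(p > 0))
    expect_true(all(diff(p) < 0))
    # geometric series closed form for the truncated mass
    expect_equal(sum(p), 1 - (1 - theta)^k)
    expect_equal(geom1_cdf(theta, k), cumsum(p))
    expect_equal(geom1_sf(theta, k), 1 - geom1_cdf(theta, k))
    # strict increase checked where the increments are representable
    expect_true(all(diff(geom1_cdf(theta, 20)) > 0))
  }
})

test_that("survival function does not underflow where 1 - cdf would", {
  expect_gt(geom1_sf(0.5, 80)[80], 0)
  expect_equal(geom1_sf(0.5, 80)[80], 0.5^80)
})

test_that("score vector is the pmf derivative and sums to Fisher information", {
  expect_equal(geom1_score(0.5, 3), c(1, 0, -0.25))
  for (theta in c(0.1, 0.37, 0.9)) {
    expect_equal(geom1_score(theta, 5)[1], 1)
    # check against numerical differentiation of the pmf
    eps <- 1e-6
    num <- (geom1_pmf(theta + eps, 8) - geom1_pmf(theta - eps, 8)) / (2 * eps)
    expect_equal(geom1_score(theta, 8), num, tolerance = 1e-6)
  }
  # sum b_j^2 / p_j increases in k towards 1 / (theta^2 (1 - theta))
  theta <- 0.5
  info <- function(k) sum(geom1_score(theta, k)^2 / geom1_pmf(theta, k))
  expect_true(all(diff(vapply(c(5, 10, 20, 50), info, numeric(1))) > 0))
  expect_equal(info(200), 8, tolerance = 1e-6)
})

test_that("theta must lie strictly inside (0, 1)", {
  expect_error(geom1_pmf(0, 3), "strictly inside")
  expect_error(geom1_pmf(1, 3), "strictly inside")
  expect_error(geom1_cdf(-0.1, 3), "strictly inside")
  expect_error(theta_wald_ci(1, 100), "strictly inside")
})

test_that("MLE is the inverse sample mean and rejects degenerate samples", {
  expect_equal(theta_mle(toy_counts()), 0.5)
  expect_equal(round(theta_mle(market_column("nasdaq")), 3), 0.512)
  expect_error(theta_mle(data.frame(value = 1, count = 10)), "[Dd]egenerate")
  expect_error(theta_mle(data.frame(value = numeric(), count = numeric())),
               "[Ee]mpty")
})

test_that("MLE recovers the parameter on large synthetic samples", {
  withr::with_seed(101, {
    for (theta in c(0.1, 0.5, 0.9)) {
      expect_lt(abs(theta_mle(rgeom1(1e5, theta)) - theta), 0.01)
    }
  })
})

test_that("delta-method interval matches published values and collapses as level -> 0", {
  expect_equal(unlist(theta_wald_ci(0.512, 1032)), c(lower = 0.490, upper = 0.534),
               tolerance = 5e-4)
  expect_equal(unlist(theta_wald_ci(0.476, 958)), c(lower = 0.454, upper = 0.498),
               tolerance = 5e-4)
  tiny <- theta_wald_ci(0.3, 50, level = 1e-10)
  expect_equal(tiny$lower, 0.3, tolerance = 1e-8)
  expect_equal(tiny$upper, 0.3, tolerance = 1e-8)
  ci <- theta_wald_ci(0.3, 50)
  expect_lt(ci$lower, 0.3)
  expect_gt(ci$upper, 0.3)
})
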