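test_that("simulation is deterministic under a seed and non-negative", {
  s1 <- simulate_statistics(0.5, 30, reps = 300, seed = 4)
  s2 <- simulate_statistics(0.5, 30, reps = 300, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$value >= 0))
  expect_true(all(s1$theta_hat > 0 & s1$theta_hat < 1))
  s3 <- simulate_statistics(0.5, 30, reps = 300, seed = 5)
  expect_false(identical(s1$value, s3$value))
})

test_that("degenerate all-ones samples are redrawn and counted", {
  # theta = 0.9, n = 4: P(all ones) = 0.9^4 = 0.656, so redraws are certain
  sims <- simulate_statistics(0.9, 4, reps = 200, seed = 8)
  expect_gt(attr(sims, "redraws"), 0)
  expect_true(all(sims$theta_hat < 1))
  # at moderate theta and n redraws essentially never happen
  sims2 <- simulate_statistics(0.3, 100, reps = 200, seed = 8)
  expect_equal(attr(sims2, "redraws"), 0L)
})

test_that("unresolvable tails and bad configs are rejected", {
  expect_error(empirical_percentage_points(0.5, 50, reps = 150,
                                           alphas = 0.01),
               "resolved")
  expect_error(simulate_statistics(0.5, 1, reps = 200), "sample size")
  expect_error(simulate_statistics(0.5, 50, reps = 10), "at least 100")
})

test_that("empirical points approach the asymptotic values as n grows", {
  # mirrors the published convergence pattern at theta = 0.9 for A2:
  # the n = 200 empirical 5% point should beat n = 25 in distance to the
  # asymptotic point, for a majority of seeds
  asym <- wchi2_quantile(eigen_spectrum("a2", 0.9, estimated = TRUE), 0.05)
  wins <- 0L
  for (seed in 1:5) {
    e25 <- empirical_percentage_points(0.9, 25, reps = 5000, alphas = 0.05,
                                       statistic = "a2", seed = seed)
    e200 <- empirical_percentage_points(0.9, 200, reps = 5000, alphas = 0.05,
                                        statistic = "a2", seed = seed)
    if (abs(e200$critical_value - asym) < abs(e25$critical_value - asym)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 3L)
})

test_that("reduced-rep empirical points sit near the published finite-n values", {
  # published: theta = 0.3, n = 50, alpha = 0.05 gives 0.264 (W2), 1.323 (A2)
  pp <- empirical_percentage_points(0.3, 50, reps = 5000, alphas = 0.05,
                                    seed = 12)
  expect_equal(pp$critical_value[pp$statistic == "w2"], 0.264,
               tolerance = 0.08)
  expect_equal(pp$critical_value[pp$statistic == "a2"], 1.323,
               tolerance = 0.08)
})
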