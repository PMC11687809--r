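test_that("end-to-end test reproduces the published market summaries", {
  fit <- gof_test(market_column("nasdaq"), pvalue = "both")
  g <- glance(fit)
  expect_equal(g$n, 1032)
  expect_equal(round(g$x_bar, 3), 1.952)
  expect_equal(round(g$theta_hat, 3), 0.512)
  td <- tidy(fit)
  expect_equal(round(td$value[td$statistic == "w2"], 3), 0.060)
  expect_equal(round(td$value[td$statistic == "a2"], 3), 0.314)
  expect_equal(td$p_label[td$statistic == "w2"], "0.25 < p < 0.50")
  expect_equal(td$p_label[td$statistic == "a2"], "p > 0.50")
  expect_false(any(td$reject))
  # continuous p-values fall inside (or beyond the open end of) the brackets
  for (i in seq_len(nrow(td))) {
    if (!is.na(td$p_lower[i])) expect_gte(td$p_value[i], td$p_lower[i])
    if (!is.na(td$p_upper[i])) expect_lte(td$p_value[i], td$p_upper[i])
  }

  fit_nik <- gof_test(market_column("nikkei"), pvalue = "bracket")
  td_nik <- tidy(fit_nik)
  expect_equal(round(td_nik$value, 3), c(0.022, 0.206))
  expect_equal(td_nik$p_label, c("p > 0.50", "p > 0.50"))
})

test_that("an exact-fit table is never rejected and reports p = 1", {
  fit <- gof_test(exact_fit_table(theta = 0.5, k = 50, n = 50))
  td <- tidy(fit)
  expect_lt(max(td$value), 1e-12)
  expect_equal(td$p_value, c(1, 1))
  expect_false(any(td$reject))
})

test_that("degenerate input and unknown alpha are rejected", {
  expect_error(gof_test(data.frame(value = 1, count = 5)), "[Dd]egenerate")
  expect_error(gof_test(toy_counts(), alpha = 0.07, pvalue = "bracket"),
               "not a level")
})

test_that("theta outside the table grid falls back to the continuous path", {
  withr::with_seed(41, {
    x <- rgeom1(400, 0.97)
    while (all(x == 1)) x <- rgeom1(400, 0.97)
  })
  expect_warning(fit <- gof_test(x), "outside")
  td <- tidy(fit)
  expect_true(all(is.na(td$p_lower)))
  expect_true(all(!is.na(td$p_value)))
  expect_true(all(!is.na(td$reject)))
})

test_that("JSON reports round-trip losslessly and formats agree", {
  fit <- gof_test(market_column("djia"), pvalue = "bracket")
  path <- withr::local_tempfile(fileext = ".json")
  write_gof_report(fit, path, format = "json")
  back <- read_gof_report(path)
  expect_equal(back$theta_hat, fit$theta_hat)
  expect_equal(back$results$value, fit$results$value)
  expect_equal(tidy(back)$reject, tidy(fit)$reject)
  expect_equal(back$data, fit$data)

  txt <- write_gof_report(fit, format = "text")
  expect_match(txt, "theta_hat = 0.506")
  expect_match(txt, "no rejection")
})

test_that("printing shows the table-style summary at 3 decimals", {
  fit <- gof_test(market_column("nasdaq"), pvalue = "bracket")
  out <- paste(capture.output(print(fit)), collapse = "\n")
  expect_match(out, "theta_hat = 0.512")
  expect_match(out, "W2 = 0.060")
  expect_match(out, "A2 = 0.314")
})

test_that("autoplot and the simulation plot return ggplot objects", {
  fit <- gof_test(toy_counts(), pvalue = "bracket")
  expect_s3_class(autoplot(fit), "ggplot")
  sims <- simulate_statistics(0.5, 40, reps = 200, seed = 2)
  expect_s3_class(plot_null_distribution(sims, 0.5, alphas = 0.05), "ggplot")
})
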