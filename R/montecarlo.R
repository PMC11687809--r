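#' Simulate the finite-sample null distribution of the statistics
#'
#' Draws `reps` samples of `n` geometric observations at the given `theta`
#' (inverse-CDF sampling, `ceiling(log(U) / log(1 - theta))`), re-estimates
#' `theta_hat = 1 / x_bar` for each sample, builds its frequency table and
#' computes the estimated-parameter statistics. Samples in which every
#' observation equals 1 leave `theta_hat` on the boundary and the statistics
#' undefined; they are redrawn, and the number of redraws is recorded in the
#' `redraws` attribute (this only occurs with noticeable frequency at large
#' `theta` and small `n`).
#'
#' @inheritParams geom1_pmf
#' @param n Sample size per replicate (`>= 2`).
#' @param reps Number of replicates (`>= 100`).
#' @param statistic `"w2"`, `"a2"` or `"both"` (default).
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A tibble with columns `rep`, `theta_hat`, `statistic`, `value`,
#'   in long form; attribute `redraws` counts redrawn degenerate samples.
#' @examples
#' sims <- simulate_statistics(0.5, n = 50, reps = 200, seed = 1)
#' dplyr::summarise(dplyr::group_by(sims, statistic), mean = mean(value))
#' @export
simulate_statistics <- function(theta, n, reps = 25000,
                                statistic = c("both", "w2", "a2"),
                                seed = NULL) {
  check_theta(theta)
  statistic <- match.arg(statistic)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a sample size >= 2.", call. = FALSE)
  }
  if (!is.numeric(reps) || length(reps) != 1L || reps < 100) {
    stop("`reps` must be at least 100.", call. = FALSE)
  }
  n <- as.integer(n)
  reps <- as.integer(reps)
  with_seed(seed, {
    x <- matrix(as.integer(ceiling(log(stats::runif(reps * n)) /
                                     log1p(-theta))), nrow = reps)
    redraws <- 0L
    w2 <- a2 <- th <- numeric(reps)
    for (r in seq_len(reps)) {
      xr <- x[r, ]
      while (all(xr == 1L)) {            # boundary MLE: redraw
        redraws <- redraws + 1L
        xr <- as.integer(ceiling(log(stats::runif(n)) / log1p(-theta)))
      }
      counts <- tabulate(xr)
      th_r <- sum(counts) / sum(seq_along(counts) * counts)
      s <- gof_stat_core(counts, th_r)
      th[r] <- th_r
      w2[r] <- s[["w2"]]
      a2[r] <- s[["a2"]]
    }
    out <- tibble::tibble(
      rep = rep(seq_len(reps), times = 2L),
      theta_hat = rep(th, times = 2L),
      statistic = rep(c("w2", "a2"), each = reps),
      value = c(w2, a2)
    )
    if (statistic != "both") {
      out <- dplyr::filter(out, .data$statistic == .env$statistic)
    }
    attr(out, "redraws") <- redraws
    out
  })
}

#' Empirical percentage points from null simulations
#'
#' Upper-tail empirical quantiles of the simulated statistic values at each
#' significance level, using linear order-statistic interpolation
#' (`stats::quantile()` type 7). At least 10 replicates must land beyond
#' the deepest requested tail, otherwise the level is unresolvable and an
#' error is raised.
#'
#' @inheritParams simulate_statistics
#' @param alphas Upper-tail levels (default the packaged table levels).
#' @return A tibble with columns `statistic`, `theta`, `n`, `reps`, `alpha`,
#'   `critical_value`.
#' @examples
#' empirical_percentage_points(0.5, n = 50, reps = 500, alphas = 0.1,
#'                             seed = 1)
#' @export
empirical_percentage_points <- function(theta, n, reps = 25000,
                                        alphas = default_alpha_levels(),
                                        statistic = c("both", "w2", "a2"),
                                        seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(all(alphas > 0), all(alphas < 1))
  if (reps * min(alphas) < 10) {
    stop("reps * min(alphas) < 10: the deepest requested tail cannot be ",
         "resolved; increase `reps`.", call. = FALSE)
  }
  sims <- simulate_statistics(theta, n, reps, statistic, seed)
  sims |>
    dplyr::group_by(.data$statistic) |>
    dplyr::reframe(
      alpha = sort(alphas, decreasing = TRUE),
      critical_value = unname(stats::quantile(
        .data$value, probs = 1 - sort(alphas, decreasing = TRUE),
        type = 7))
    ) |>
    dplyr::mutate(theta = theta, n = n, reps = reps,
                  .after = "statistic")
}
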