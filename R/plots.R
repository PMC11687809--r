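#' Plot observed versus fitted geometric frequencies
#'
#' Bars show the observed counts per run length (or outcome value); points
#' and a line show the expected counts `n * p_i(theta_hat)` under the
#' fitted geometric model. Large systematic gaps between the two are what
#' the test statistics accumulate.
#'
#' @param object A `geom_gof` object from [gof_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' runs <- market_runs()
#' fit <- gof_test(data.frame(value = runs$length, count = runs$nasdaq),
#'                 pvalue = "bracket")
#' autoplot(fit)
#' @export
autoplot.geom_gof <- function(object, ...) {
  dev <- cumulative_deviations(object$data, object$theta_hat)
  ggplot2::ggplot(dev, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "#2166ac") +
    ggplot2::labs(
      x = "outcome value", y = "count",
      title = "Observed vs fitted geometric frequencies",
      subtitle = sprintf("theta_hat = %.3f, n = %d", object$theta_hat,
                         object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated null distributions against asymptotic percentage points
#'
#' Histograms of the simulated statistic values from
#' [simulate_statistics()], with vertical lines at selected asymptotic
#' upper-tail quantiles computed from the eigen spectrum at the simulating
#' `theta`, visualising how fast the finite-sample null approaches its
#' asymptotic limit.
#'
#' @param sims Output of [simulate_statistics()].
#' @param theta The `theta` the simulation was run at.
#' @param alphas Tail levels to mark.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(sims, theta, alphas = c(0.05, 0.01)) {
  marks <- purrr::map_dfr(unique(sims$statistic), function(st) {
    sp <- eigen_spectrum(st, theta, estimated = TRUE)
    tibble::tibble(statistic = st, alpha = alphas,
                   q = wchi2_quantile(sp, alphas))
  })
  ggplot2::ggplot(sims, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey70") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$q,
                                     linetype = factor(.data$alpha)),
                        colour = "#b2182b") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "statistic value", y = "replicates",
                  linetype = "upper-tail level",
                  title = "Simulated null distribution vs asymptotic points") +
    ggplot2::theme_minimal()
}
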