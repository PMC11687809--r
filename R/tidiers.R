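#' Tidy a geometric goodness-of-fit test
#'
#' `tidy()` returns one row per computed statistic with its value, bracket
#' bounds, continuous p-value, critical value at the test's `alpha` and the
#' rejection decision. `glance()` returns a one-row summary of the fitted
#' model (sample size, mean, `theta_hat` and its confidence interval).
#'
#' @param x A `geom_gof` object from [gof_test()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' runs <- market_runs()
#' fit <- gof_test(data.frame(value = runs$length, count = runs$nasdaq),
#'                 pvalue = "bracket")
#' tidy(fit)
#' glance(fit)
#' @export
tidy.geom_gof <- function(x, ...) {
  x$results
}

#' @rdname tidy.geom_gof
#' @export
glance.geom_gof <- function(x, ...) {
  tibble::tibble(
    n = x$n, x_bar = x$x_bar, theta_hat = x$theta_hat,
    ci_lower = x$ci$lower, ci_upper = x$ci$upper, level = x$level,
    k = nrow(x$data), alpha = x$alpha
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
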