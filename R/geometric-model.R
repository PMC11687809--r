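#' Geometric probability model (support starting at 1)
#'
#' The package works throughout with the "number of trials until the first
#' success" convention: a geometric random variable `X` takes values
#' `i = 1, 2, ...` with `P(X = i) = (1 - theta)^(i-1) * theta`, where
#' `theta` is the per-trial success probability. Note this differs from
#' [stats::dgeom()], which counts failures before the first success
#' (support starting at 0).
#'
#' `geom1_pmf()` returns the first `k` probability masses, `geom1_cdf()` the
#' distribution function `H_i = 1 - (1 - theta)^i`, and `geom1_sf()` the
#' survival function `1 - H_i = (1 - theta)^i`, computed directly so it does
#' not underflow through cancellation for large `i`. `geom1_score()` returns
#' the derivative of each mass with respect to `theta`,
#' `b_j = (1 - theta)^(j-2) * (1 - j * theta)`, the score vector used in the
#' MLE correction of the asymptotic covariance. `rgeom1()` draws samples by
#' inversion, `ceiling(log(U) / log(1 - theta))`.
#'
#' @param theta Success probability, strictly inside (0, 1).
#' @param k Number of leading support points to evaluate (positive integer).
#' @param n Number of draws.
#' @return For the vector functions, a numeric vector of length `k`;
#'   for `rgeom1()`, an integer vector of length `n` with values `>= 1`.
#' @examples
#' geom1_pmf(0.5, 3)            # 0.5 0.25 0.125
#' geom1_cdf(0.5, 4)            # 0.5 0.75 0.875 0.9375
#' geom1_score(0.5, 3)          # 1 0 -0.25
#' sum(geom1_score(0.5, 200)^2 / geom1_pmf(0.5, 200))  # Fisher information, 8
#' @name geometric-model
NULL

check_theta <- function(theta, arg = "theta") {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("`", arg, "` must be a single finite number.", call. = FALSE)
  }
  if (theta <= 0 || theta >= 1) {
    stop("`", arg, "` must lie strictly inside (0, 1); got ", theta,
         ". Boundary values make the geometric model degenerate.",
         call. = FALSE)
  }
  invisible(theta)
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 ||
      k != trunc(k)) {
    stop("`k` must be a positive integer.", call. = FALSE)
  }
  as.integer(k)
}

#' @rdname geometric-model
#' @export
geom1_pmf <- function(theta, k) {
  check_theta(theta)
  k <- check_k(k)
  (1 - theta)^(seq_len(k) - 1) * theta
}

#' @rdname geometric-model
#' @export
geom1_cdf <- function(theta, k) {
  check_theta(theta)
  k <- check_k(k)
  1 - (1 - theta)^seq_len(k)
}

#' @rdname geometric-model
#' @export
geom1_sf <- function(theta, k) {
  check_theta(theta)
  k <- check_k(k)
  (1 - theta)^seq_len(k)
}

#' @rdname geometric-model
#' @export
geom1_score <- function(theta, k) {
  check_theta(theta)
  k <- check_k(k)
  j <- seq_len(k)
  (1 - theta)^(j - 2) * (1 - j * theta)
}

#' @rdname geometric-model
#' @export
rgeom1 <- function(n, theta) {
  check_theta(theta)
  as.integer(ceiling(log(stats::runif(n)) / log1p(-theta)))
}

#' Maximum-likelihood estimate of the geometric success probability
#'
#' The MLE is the inverse of the sample mean, `theta_hat = 1 / x_bar`,
#' computed here from a frequency table as `sum(count) / sum(value * count)`.
#'
#' @param data A frequency table: anything accepted by [as_freq_table()]
#'   (a data frame with `value`/`count` columns, or a raw vector of
#'   positive-integer observations).
#' @return The estimate, a single number in (0, 1).
#' @details A sample with all mass at value 1 has `x_bar = 1` and puts the
#'   estimate on the boundary `theta_hat = 1`, where the test statistics and
#'   the asymptotic theory are undefined; such samples are rejected with an
#'   error rather than silently clamped.
#' @examples
#' theta_mle(c(1, 1, 2, 4))  # x_bar = 2, so 0.5
#' @export
theta_mle <- function(data) {
  tab <- as_freq_table(data)
  n <- sum(tab$count)
  m <- sum(tab$value * tab$count) / n
  if (m <= 1) {
    stop("Degenerate sample: every observation equals 1, so theta_hat = 1 ",
         "lies on the boundary and the goodness-of-fit statistics are ",
         "undefined.", call. = FALSE)
  }
  1 / m
}

#' Delta-method (Wald) confidence interval for the geometric parameter
#'
#' Interval `theta_hat +/- z * sqrt(theta_hat^2 * (1 - theta_hat) / n)` with
#' `z` the `(1 + level) / 2` standard normal quantile, using the asymptotic
#' variance of `theta_hat = 1 / x_bar` obtained by the delta method from
#' `Var(x_bar) = (1 - theta) / (n theta^2)`. Endpoints are clipped to (0, 1).
#'
#' @param theta_hat Point estimate, strictly inside (0, 1).
#' @param n Sample size (number of observations behind `theta_hat`).
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `lower`, `upper`.
#' @examples
#' theta_wald_ci(0.512, 1032)  # approximately [0.490, 0.534]
#' @export
theta_wald_ci <- function(theta_hat, n, level = 0.95) {
  check_theta(theta_hat, "theta_hat")
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single sample size >= 2.", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must lie strictly inside (0, 1).", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(theta_hat^2 * (1 - theta_hat) / n)
  tibble::tibble(
    lower = max(theta_hat - half, .Machine$double.xmin),
    upper = min(theta_hat + half, 1 - .Machine$double.eps)
  )
}
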