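#' Cumulative deviations between observed and expected frequencies
#'
#' For a frequency table with counts `o_i` over cells `1..k` and a geometric
#' model with parameter `theta`, the expected counts are `e_i = n p_i(theta)`
#' and the cumulative deviation process is `Z_j = S_j - T_j` with
#' `S_j = sum(o_i, i <= j)` and `T_j = sum(e_i, i <= j) = n H_j`. `T` is
#' computed from the closed-form distribution function rather than by summing
#' the pmf, which limits cancellation in `Z` for large `k`. Both discrete
#' test statistics are quadratic forms in `Z`.
#'
#' @inheritParams theta_mle
#' @param theta Success probability of the hypothesised geometric model,
#'   strictly inside (0, 1).
#' @return A tibble with one row per cell `1..k` and columns `value`,
#'   `observed`, `expected`, `S`, `T`, `Z`, `H`.
#' @examples
#' cumulative_deviations(c(1, 1, 2, 4), theta = 0.5)
#' @export
cumulative_deviations <- function(data, theta) {
  tab <- as_freq_table(data)
  check_theta(theta)
  k <- k_cells(tab)
  n <- n_obs(tab)
  H <- geom1_cdf(theta, k)
  tibble::tibble(
    value = tab$value,
    observed = tab$count,
    expected = n * geom1_pmf(theta, k),
    S = cumsum(tab$count),
    T = n * H,
    Z = cumsum(tab$count) - n * H,
    H = H
  )
}

# shared numeric core: takes a dense count vector, returns both statistics
gof_stat_core <- function(counts, theta) {
  k <- length(counts)
  n <- sum(counts)
  p <- (1 - theta)^(seq_len(k) - 1) * theta
  Hbar <- (1 - theta)^seq_len(k)     # survival function, no cancellation
  Z <- cumsum(counts) - n * (1 - Hbar)
  c(w2 = sum(Z^2 * p) / n,
    a2 = sum(Z^2 * p / ((1 - Hbar) * Hbar)) / n)
}

#' Discrete Watson and Anderson-Darling statistics
#'
#' The discrete Watson statistic is
#' `W^2 = n^-1 sum(Z_i^2 p_i(theta), i = 1..k)` and the discrete
#' Anderson-Darling statistic reweights each term by the variance of the
#' empirical distribution function,
#' `A^2 = n^-1 sum(Z_i^2 p_i(theta) / (H_i (1 - H_i)), i = 1..k)`,
#' where `k` is the last non-empty cell of the observed table. When `theta`
#' is omitted it is replaced by the maximum-likelihood estimate
#' `theta_hat = 1 / x_bar`, giving the estimated-parameter statistics whose
#' null distribution differs from the known-parameter case (see
#' [eigen_spectrum()]).
#'
#' @inheritParams cumulative_deviations
#' @param theta Hypothesised success probability; `NULL` (default) estimates
#'   it from the data by maximum likelihood.
#' @return A single non-negative number.
#' @examples
#' watson_w2(c(1, 1, 2, 4), theta = 0.5)            # 0.0087890625
#' anderson_darling_a2(c(1, 1, 2, 4), theta = 0.5)  # 0.08809524
#' @seealso [gof_statistics()] for both at once, [gof_test()] for the full
#'   test procedure with p-values.
#' @export
watson_w2 <- function(data, theta = NULL) {
  gof_statistics(data, theta)$value[1]
}

#' @rdname watson_w2
#' @export
anderson_darling_a2 <- function(data, theta = NULL) {
  gof_statistics(data, theta)$value[2]
}

#' Both goodness-of-fit statistics for one dataset
#'
#' @inheritParams watson_w2
#' @return A tibble with columns `statistic` (`"w2"`, `"a2"`), `value`,
#'   `theta` (the value actually used) and `estimated` (whether `theta` was
#'   estimated from the data).
#' @examples
#' gof_statistics(c(1, 1, 2, 4))
#' @export
gof_statistics <- function(data, theta = NULL) {
  tab <- as_freq_table(data)
  estimated <- is.null(theta)
  if (estimated) {
    theta <- theta_mle(tab)
  } else {
    check_theta(theta)
  }
  s <- gof_stat_core(tab$count, theta)
  tibble::tibble(
    statistic = c("w2", "a2"),
    value = unname(s),
    theta = theta,
    estimated = estimated
  )
}
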