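#' Asymptotic covariance of the cumulative-deviation process
#'
#' For a truncated geometric model over cells `1..k` the vector of observed
#' counts is multinomial, so the scaled deviations `(o - e) / sqrt(n)` have
#' limiting covariance `Sigma_0 = D - P P'`, with `D = diag(p_1, ..., p_k)`
#' and `P` the pmf vector. The cumulative deviations are `Z = R (o - e)`
#' with `R` the unit lower-triangular partial-sum matrix, giving
#' `Sigma = R Sigma_0 R'`, whose entries equal
#' `min(H_i, H_j) - H_i H_j` in closed form.
#'
#' When `theta` is estimated by maximum likelihood, the covariance of the
#' cell deviations shrinks by a rank-one term:
#' `Sigma_0_hat = Sigma_0 - b b' / (b' D^-1 b)`, where `b_j = dp_j/dtheta`
#' is the score vector ([geom1_score()]) and `b' D^-1 b` converges to the
#' Fisher information `1 / (theta^2 (1 - theta))` as `k` grows.
#' `covariance_estimated()` returns `R Sigma_0_hat R'`.
#'
#' @inheritParams geom1_pmf
#' @return A `k x k` symmetric matrix.
#' @examples
#' covariance_known(0.5, 2)[1, 2]  # min(H1, H2) - H1*H2 = 0.125
#' @export
covariance_known <- function(theta, k) {
  partial_sum_cov(theta, k, estimated = FALSE)
}

#' @rdname covariance_known
#' @export
covariance_estimated <- function(theta, k) {
  partial_sum_cov(theta, k, estimated = TRUE)
}

partial_sum_cov <- function(theta, k, estimated) {
  check_theta(theta)
  k <- check_k(k)
  p <- geom1_pmf(theta, k)
  S0 <- diag(p, k) - tcrossprod(p)
  if (estimated) {
    b <- geom1_score(theta, k)
    S0 <- S0 - tcrossprod(b) / score_info(theta, k)
  }
  # R S0 R' via cumulative sums down rows then across columns
  M <- apply(apply(S0, 2, cumsum), 1, cumsum)
  (M + t(M)) / 2
}

# b' D^-1 b = sum b_j^2 / p_j, accumulated termwise as
# (1 - theta)^(j - 3) (1 - j theta)^2 / theta so deep cells underflow to
# zero instead of producing 0/0 when p_j itself underflows
score_info <- function(theta, k) {
  j <- seq_len(k)
  sum((1 - theta)^(j - 3) * (1 - j * theta)^2 / theta)
}

#' Diagonal weight matrix of the quadratic form
#'
#' Both statistics are `Z' V Z / n` with diagonal `V`: the Watson statistic
#' uses `V = D` (entries `p_i`) and the Anderson-Darling statistic
#' `V = D G^-1` (entries `p_i / (H_i (1 - H_i))`, `G` the diagonal matrix of
#' empirical-CDF variances).
#'
#' @param statistic `"w2"` (Watson) or `"a2"` (Anderson-Darling).
#' @inheritParams geom1_pmf
#' @return A `k x k` diagonal matrix with positive diagonal.
#' @export
weight_matrix <- function(statistic = c("w2", "a2"), theta, k) {
  statistic <- match.arg(statistic)
  diag(weight_diag(statistic, theta, k), check_k(k))
}

weight_diag <- function(statistic, theta, k) {
  p <- geom1_pmf(theta, k)
  if (statistic == "w2") {
    p
  } else {
    Hbar <- geom1_sf(theta, k)
    p / ((1 - Hbar) * Hbar)
  }
}

#' Eigenvalue spectrum of the asymptotic null distribution
#'
#' The null distribution of `n` times either statistic converges to a
#' weighted sum of independent squared standard normals,
#' `Q = sum(lambda_i nu_i^2)`, where the weights are the eigenvalues of
#' `Sigma_X = V^(1/2) Sigma V^(1/2)` (`Sigma` replaced by its MLE-corrected
#' version when `theta` is estimated). Since `V` is diagonal, `Sigma_X` is
#' formed by elementwise scaling and handed to a symmetric eigensolver.
#' Eigenvalues below `1e-10 * lambda_max` (numerical noise, plus the exact
#' rank reduction from the one-parameter correction) are clipped to zero.
#'
#' If `k` is `NULL` the truncation index is chosen by [choose_truncation()].
#'
#' @inheritParams weight_matrix
#' @param estimated Whether `theta` is treated as estimated by maximum
#'   likelihood (the usual case) or known a priori.
#' @param k Truncation index, or `NULL` to choose automatically.
#' @param alpha Tail level used by the automatic truncation rule.
#' @return An object of class `eigen_spectrum`: a list with elements
#'   `lambdas` (descending, clipped at zero), `statistic`, `theta`,
#'   `estimated`, `k`, and `trace` (of the matrix before clipping).
#' @examples
#' sp <- eigen_spectrum("w2", theta = 0.5, estimated = TRUE, k = 34)
#' sum(sp$lambdas)  # equals the matrix trace to rounding
#' @export
eigen_spectrum <- function(statistic = c("w2", "a2"), theta,
                           estimated = TRUE, k = NULL, alpha = 0.05) {
  statistic <- match.arg(statistic)
  check_theta(theta)
  if (is.null(k)) {
    k <- choose_truncation(statistic, theta, estimated, alpha)
  }
  k <- check_k(k)
  lam <- spectrum_lambdas(statistic, theta, estimated, k)
  structure(
    list(lambdas = lam$lambdas, statistic = statistic, theta = theta,
         estimated = estimated, k = k, trace = lam$trace,
         sum_raw = lam$sum_raw),
    class = "eigen_spectrum"
  )
}

spectrum_lambdas <- function(statistic, theta, estimated, k) {
  Sig <- partial_sum_cov(theta, k, estimated)
  sq <- sqrt(weight_diag(statistic, theta, k))
  M <- Sig * tcrossprod(sq)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum_raw <- sum(ev)
  ev[ev < 1e-10 * max(ev)] <- 0
  list(lambdas = sort(ev, decreasing = TRUE), trace = sum(diag(M)),
       sum_raw = sum_raw)
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf(
    "<eigen_spectrum> %s, theta = %g, %s, k = %d\n",
    if (x$statistic == "w2") "Watson W2" else "Anderson-Darling A2",
    x$theta, if (x$estimated) "estimated theta" else "known theta", x$k))
  cat(sprintf("  %d positive eigenvalues, sum = %.6g, largest = %.6g\n",
              sum(x$lambdas > 0), sum(x$lambdas), x$lambdas[1]))
  invisible(x)
}

#' Truncation index for the asymptotic computation
#'
#' The infinite geometric support must be cut at some `k`. The rule combines
#' a probability-mass floor -- `k` large enough that the residual mass
#' `(1 - theta)^k` is below `1e-10` -- with an empirical convergence check:
#' `k` is doubled until the upper `alpha` quantile of the weighted
#' chi-square limit changes by less than `tol` between successive values.
#'
#' @inheritParams eigen_spectrum
#' @param tol Quantile convergence tolerance between successive `k`.
#' @param k_max Hard cap; exceeding it raises an error (cannot happen for
#'   `theta >= 0.01`; guards pathological inputs).
#' @return The chosen truncation index (integer).
#' @examples
#' choose_truncation("w2", 0.5, estimated = TRUE, alpha = 0.05)
#' @export
choose_truncation <- function(statistic = c("w2", "a2"), theta,
                              estimated = TRUE, alpha = 0.05,
                              tol = 5e-5, k_max = 5000) {
  statistic <- match.arg(statistic)
  truncation_details(statistic, theta, estimated, alpha, tol, k_max)$k
}

# returns the converged k together with its spectrum and target quantile,
# so callers that need the spectrum do not recompute the eigenproblem
truncation_details <- function(statistic, theta, estimated, alpha,
                               tol = 5e-5, k_max = 5000) {
  check_theta(theta)
  k <- max(ceiling(log(1e-10) / log1p(-theta)), 5L)
  lam <- spectrum_lambdas(statistic, theta, estimated, k)
  q_prev <- wchi2_quantile(lam$lambdas, alpha)
  repeat {
    k2 <- 2L * k
    if (k2 > k_max) {
      stop("Truncation did not converge below k_max = ", k_max,
           " (theta = ", theta, ").", call. = FALSE)
    }
    lam2 <- spectrum_lambdas(statistic, theta, estimated, k2)
    q2 <- wchi2_quantile(lam2$lambdas, alpha)
    if (abs(q2 - q_prev) < tol) {
      return(list(k = k2, lambdas = lam2$lambdas, trace = lam2$trace,
                  quantile = q2))
    }
    k <- k2
    q_prev <- q2
  }
}
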