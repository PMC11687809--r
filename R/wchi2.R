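#' Weighted sums of squared standard normals
#'
#' The asymptotic null law of both test statistics is a quadratic form
#' `Q = sum(lambda_i nu_i^2)` with `nu_i` independent standard normals and
#' non-negative weights `lambda_i` (the eigenvalues from
#' [eigen_spectrum()]). `wchi2_tail()` evaluates `P(Q > q)` by numerical
#' inversion of the characteristic function (the Gil-Pelaez/Imhof integral),
#' `wchi2_quantile()` inverts it by bracketed root search, and
#' `wchi2_sample()` draws from `Q` directly as an independent Monte Carlo
#' check on the quadrature.
#'
#' The inversion integral
#' `P(Q > q) = 1/2 + (1/pi) * integral_0^inf sin(psi(u)) / (u rho(u)) du`,
#' with phase `psi(u) = sum(atan(lambda_i u))/2 - q u / 2` and modulus
#' `rho(u) = prod(1 + lambda_i^2 u^2)^(1/4)`, is computed by adaptive
#' Gauss-Kronrod quadrature on segments of `[0, U]` sized to a bounded
#' number of oscillation periods, plus a closed-form two-term
#' integration-by-parts correction for the remainder beyond `U`; `U` grows
#' until the correction's own error estimate is below `tol / 10`. This
#' handles the slowly decaying oscillatory integrand that arises with few
#' eigenvalues (a single weight gives the chi-square(1) tail), where naive
#' quadrature to infinity fails.
#'
#' @param lambdas Non-negative weights, at least one positive. Zero weights
#'   are dropped. An [eigen_spectrum()] object is also accepted.
#' @param q Non-negative evaluation point.
#' @param tol Absolute accuracy target for the tail probability.
#' @return `wchi2_tail()`: `P(Q > q)` in `[0, 1]`.
#' @examples
#' wchi2_tail(1, qchisq(0.95, df = 1))          # 0.05
#' wchi2_tail(c(0.5, 0.5), -log(0.05))          # 0.05 (exponential closed form)
#' wchi2_quantile(1, 0.5)                       # median of chi-square(1)
#' @export
wchi2_tail <- function(lambdas, q, tol = 1e-8) {
  lam <- clean_lambdas(lambdas)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0) {
    stop("`q` must be a single non-negative number.", call. = FALSE)
  }
  if (q == 0) {
    return(1)
  }
  # far below the distribution's scale the lower-tail mass is provably
  # negligible: P(Q <= q) <= prod_i P(lambda_i nu_i^2 <= q)
  if (prod(2 * stats::pnorm(sqrt(q / lam)) - 1) < tol / 10) {
    return(1)
  }
  U <- 10 / max(lam)
  repeat {
    tc <- imhof_tail_corr(U, lam, q)
    if (tc$err < tol / 10 || U > 1e8) break
    U <- 2 * U
  }
  seg <- min(U, max(1, 40 * pi / q))
  edges <- unique(c(seq(0, U, by = seg), U))
  total <- 0
  for (i in seq_len(length(edges) - 1L)) {
    total <- total + stats::integrate(
      imhof_integrand, edges[i], edges[i + 1L], lam = lam, q = q,
      rel.tol = 1e-10, abs.tol = tol / 10, subdivisions = 500L)$value
  }
  min(1, max(0, 0.5 + (total + tc$val) / pi))
}

clean_lambdas <- function(lambdas) {
  if (inherits(lambdas, "eigen_spectrum")) {
    lambdas <- lambdas$lambdas
  }
  if (!is.numeric(lambdas) || length(lambdas) == 0L ||
      any(!is.finite(lambdas)) || any(lambdas < 0)) {
    stop("`lambdas` must be a non-empty vector of finite non-negative ",
         "weights.", call. = FALSE)
  }
  lam <- lambdas[lambdas > 0]
  if (length(lam) == 0L) {
    stop("All weights are zero; the quadratic form is degenerate.",
         call. = FALSE)
  }
  lam
}

imhof_integrand <- function(u, lam, q) {
  psi <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * q * u
  lrho <- 0.25 * colSums(log1p(outer(lam^2, u^2)))
  out <- sin(psi) / (u * exp(lrho))
  out[u == 0] <- 0.5 * (sum(lam) - q)
  out
}

# analytic remainder of the inversion integral beyond U: two integrations
# by parts against the phase, valid once psi'(u) is bounded away from zero
# (psi' -> -q/2 for large u); err is a crude magnitude bound on the next term
imhof_tail_corr <- function(U, lam, q) {
  lu2 <- lam^2 * U^2
  g <- 1 / (U * exp(0.25 * sum(log1p(lu2))))
  dpsi <- 0.5 * sum(lam / (1 + lu2)) - 0.5 * q
  ddpsi <- -sum(lam^3 * U / (1 + lu2)^2)
  dg <- -g * (1 / U + 0.5 * sum(lam^2 * U / (1 + lu2)))
  h <- (dg * dpsi - g * ddpsi) / dpsi^2
  psiU <- 0.5 * sum(atan(lam * U)) - 0.5 * q * U
  list(val = cos(psiU) * g / dpsi - sin(psiU) * h / dpsi,
       err = abs(h / dpsi) * 3 / U)
}

#' @rdname wchi2_tail
#' @param alpha Upper-tail probability (may be a vector), strictly in (0, 1).
#' @return `wchi2_quantile()`: the value(s) `q` with `P(Q > q) = alpha`.
#' @export
wchi2_quantile <- function(lambdas, alpha, tol = 1e-8) {
  lam <- clean_lambdas(lambdas)
  if (any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly inside (0, 1).", call. = FALSE)
  }
  vapply(alpha, function(a) {
    # bracket from a Satterthwaite moment match, then expand
    scale <- sum(lam^2) / sum(lam)
    df <- sum(lam)^2 / sum(lam^2)
    guess <- scale * stats::qchisq(a, df, lower.tail = FALSE)
    lo <- hi <- max(guess, .Machine$double.eps)
    while (wchi2_tail(lam, lo, tol) <= a) lo <- lo / 2
    while (wchi2_tail(lam, hi, tol) > a) hi <- hi * 2
    stats::uniroot(function(q) wchi2_tail(lam, q, tol) - a,
                   lower = lo, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname wchi2_tail
#' @param reps Number of Monte Carlo draws (`>= 1000`).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the draws are reproducible.
#' @return `wchi2_sample()`: a numeric vector of `reps` draws of `Q`.
#' @export
wchi2_sample <- function(lambdas, reps, seed = NULL) {
  lam <- clean_lambdas(lambdas)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1000) {
    stop("`reps` must be at least 1000.", call. = FALSE)
  }
  reps <- as.integer(reps)
  with_seed(seed, {
    nu2 <- matrix(stats::rnorm(reps * length(lam))^2, nrow = length(lam))
    as.numeric(crossprod(lam, nu2))
  })
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
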