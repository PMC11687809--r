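---
title: "Testing geometric goodness of fit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing geometric goodness of fit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomgof)
```

## The testing problem

A sample of positive integers $x_1, \dots, x_n$ — in the motivating
application, the lengths in days of uninterrupted upward or downward price
runs of a market index — is hypothesised to come from a geometric
distribution with unknown success probability $\theta$,
$$p_i(\theta) = (1-\theta)^{i-1}\theta, \qquad i = 1, 2, \dots$$
The package tests this null with discrete analogues of two classical
empirical-distribution-function statistics. With observed cell counts
$o_i$ over the cells $1..k$ ($k$ the last non-empty cell), expected counts
$e_i = n\,p_i(\hat\theta)$ and cumulative deviations
$Z_j = \sum_{i \le j}(o_i - e_i)$, the statistics are
$$W^2(\hat\theta) = n^{-1}\sum_{i=1}^k Z_i^2\, p_i(\hat\theta), \qquad
  A^2(\hat\theta) = n^{-1}\sum_{i=1}^k
  \frac{Z_i^2\, p_i(\hat\theta)}{H_i(1-H_i)},$$
where $H_i = 1-(1-\theta)^i$ is the model CDF and
$\hat\theta = 1/\bar X$ is the maximum-likelihood estimate. The
Anderson-Darling weight $1/(H_i(1-H_i))$ standardises each cumulative
deviation by its binomial variance, which emphasises the tails; the Watson
form weighs by the cell probability alone.

Interior zero-count cells below $k$ are retained — they still carry
deviation terms — while cells above $k$ are excluded, so $k$ is always
defined by the data, not by the caller. This matters in practice: the
published DJIA run-length column has an empty cell at length 11 with a
count at 12, and the IPC column empty cells at 11 and 12 with a count
at 13.

## Asymptotic null distribution

The cell counts are multinomial, so $(o - e)/\sqrt n$ has limiting
covariance $\Sigma_0 = D - PP^\top$ ($D = \mathrm{diag}(p_i)$). The
cumulative deviations are $Z = R(o-e)$ with $R$ the unit lower-triangular
partial-sum matrix, giving $\Sigma = R\Sigma_0 R^\top$, whose entries
equal $\min(H_i,H_j) - H_iH_j$ — the package tests both constructions
against each other. Estimating the single parameter by maximum likelihood
shrinks the covariance by the rank-one term
$bb^\top / (b^\top D^{-1} b)$, where $b_j = \mathrm d p_j/\mathrm d\theta
= (1-\theta)^{j-2}(1 - j\theta)$ and $b^\top D^{-1}b$ converges to the
Fisher information $1/(\theta^2(1-\theta))$ as $k$ grows.

Each statistic is a quadratic form $Z^\top V Z/n$ with diagonal weight
$V = D$ (Watson) or $V = DG^{-1}$, $G = \mathrm{diag}(H_i(1-H_i))$
(Anderson-Darling). Its null law converges to
$Q = \sum_i \lambda_i \nu_i^2$ with $\nu_i$ i.i.d. standard normal and
$\lambda_i$ the eigenvalues of $V^{1/2}\Sigma V^{1/2}$ (the MLE-corrected
$\Sigma$ in the estimated case). Because $V$ is diagonal the matrix is
symmetrised elementwise and handed to a dense symmetric eigensolver; no
generalised eigenproblem is needed. The one-parameter correction removes
one degree of freedom, so estimated-mode spectra always contain a
numerically zero eigenvalue.

### Numerical choices

* **Survival function.** $1 - H_i$ is computed directly as $(1-\theta)^i$.
  The naive `1 - cdf` cancels catastrophically: at $\theta = 0.5$ it
  underflows to exactly zero near $k = 68$ and would break the
  Anderson-Darling weight. The same closed form is used for the expected
  cumulative counts $T_j = nH_j$, limiting cancellation in $Z$.
* **Eigenvalue clipping.** Eigenvalues below $10^{-10}\lambda_{\max}$ are
  clipped to zero. At these conditioning levels the clipped mass is pure
  numerical noise (the tests assert it never exceeds $10^{-6}$ of the
  trace).
* **Truncation $k$.** The infinite support is cut where the residual mass
  $(1-\theta)^k$ drops below $10^{-10}$, and $k$ is then doubled until the
  target upper quantile moves by less than $5\times10^{-5}$. At
  $\theta = 0.5$ this gives $k = 68$; at $\theta = 0.05$, $k = 898$. A
  hard cap at $k = 5000$ guards pathological inputs only.
* **Score sum.** $b^\top D^{-1}b$ is accumulated termwise as
  $(1-\theta)^{j-3}(1-j\theta)^2/\theta$, so that deep cells underflow
  harmlessly to zero instead of producing 0/0.

## Tail probabilities of $\sum \lambda_i \nu_i^2$

Upper-tail probabilities are computed by numerical inversion of the
characteristic function (the Gil-Pelaez/Imhof integral)
$$P(Q > q) = \frac12 + \frac1\pi \int_0^\infty
  \frac{\sin\psi(u)}{u\,\rho(u)}\,\mathrm du, \qquad
  \psi(u) = \tfrac12\sum_i \arctan(\lambda_i u) - \tfrac{qu}2,\quad
  \rho(u) = \prod_i (1+\lambda_i^2u^2)^{1/4}.$$
The integrand oscillates with an envelope decaying like
$u^{-(r/2+1)}$ for $r$ positive eigenvalues; for small $r$ (the
single-weight case is the $\chi^2_1$ tail) the decay is too slow for
blind adaptive quadrature to infinity. The evaluator therefore integrates
$[0, U]$ by Gauss-Kronrod quadrature on segments capped at a bounded
number of oscillation periods, and appends a closed-form remainder for
$[U, \infty)$ obtained from two integrations by parts against the phase
(valid because $\psi'(u) \to -q/2$), enlarging $U$ until the remainder's
own error estimate is below a tenth of the $10^{-8}$ accuracy target.
Quantiles invert the tail by bracketed root search started from a
Satterthwaite (moment-matched scaled chi-square) guess. For $q$ far below
the distribution's scale the evaluator returns 1 outright, justified by
the bound $P(Q \le q) \le \prod_i P(\lambda_i\nu_i^2 \le q)$.

The evaluator is validated three ways: against the $\chi^2_1$ and
$0.5\chi^2_2$ (exponential) closed forms to $10^{-6}$; against its own
seeded Monte Carlo sampler within three binomial standard errors; and
against the complete published grids of asymptotic percentage points,
where every cell of both tables reproduces within $\pm 0.01$ (the largest
observed cell error is 0.007 for $A^2$, 0.0008 for $W^2$; the published
values themselves claim two-to-three-decimal accuracy from a
moment-matching method, so agreement beyond that is not expected).

## Critical-value tables, brackets, and p-values

`critical_value_table()` regenerates the percentage-point grids over
$\theta \in \{0.05, \dots, 0.95\}$ (with extra resolution near 0.5, where
the run-length application lives) at the seven conventional levels
$\alpha \in \{0.50, 0.25, 0.15, 0.10, 0.05, 0.025, 0.01\}$. A
pre-generated copy ships as a plain CSV and backs the table-lookup path
offline; `data-raw/make_critical_values.R` regenerates it in about ten
seconds.

Two reporting paths coexist deliberately:

* `pvalue_bracket()` mimics table-based practice: critical values are
  linearly interpolated in $\theta$ between adjacent grid rows, and the
  pair of adjacent tabulated levels straddling the observed statistic is
  reported (e.g. `0.25 < p < 0.50`). Linear interpolation is a design
  choice; nearest-row lookup gives the same brackets on all the market
  examples, so nothing here hinges on it.
* `continuous_pvalue()` performs a fresh eigen-decomposition at
  $\hat\theta$ itself and evaluates the exact asymptotic tail — finer than
  any bracket and free of interpolation error. The bracket always contains
  it (up to the table's own accuracy), which the tests assert on the
  market data.

One borderline case is instructive: the NASDAQ $A^2 = 0.3141$ sits within
0.001 of the interpolated 50% point at $\hat\theta = 0.512$; the
continuous p-value of 0.502 settles it on the `p > 0.50` side.

## Finite-sample behaviour by simulation

`simulate_statistics()` draws geometric samples by inverse-CDF sampling
($\lceil \ln U / \ln(1-\theta) \rceil$), re-estimates $\hat\theta$ per
replicate, and recomputes both statistics, mirroring the data-generating
story rather than simulating multinomial cell counts directly. Samples
that come out all ones leave $\hat\theta$ on the boundary where the
statistics are undefined; they are redrawn and counted in a `redraws`
attribute. This is a real phenomenon, not a corner case: at
$\theta = 0.9$, $n = 25$, about 7% of samples are degenerate. How such
samples were handled in the published simulations is not stated; redrawing
(i.e. conditioning the null distribution on a non-degenerate sample) is
this package's choice and is reported transparently.

Empirical percentage points use type-7 order-statistic interpolation; at
25000 replicates the difference between quantile conventions is far below
Monte Carlo noise. The default of 25000 replicates matches the published
simulations; the convergence-diagnostic tests use 5000 with widened
tolerances to keep the suite fast, and the acceptance checks use the full
25000 (about one second per configuration).

## Run-length extraction

`runs_from_series()` turns a price (or any numeric) series into maximal
same-direction streaks of first differences; run length is the number of
moves in the streak. Ties (zero differences) have no direction, and the
original construction does not document their treatment, so the policy is
a required argument with no default: `"error"` refuses tied series,
`"break"` lets a tie terminate the current run, `"drop"` removes the tied
observation. The packaged worked example starts from the published
frequency columns, so no conclusion in the documentation depends on this
choice.

## What the synthetic data does and does not show

The generator draws i.i.d. geometric lengths with a constant $\theta$ —
exactly the null hypothesis. Passing calibration tests (type-I error
5% ± 1.5% at $\alpha = 0.05$ over 2000 null datasets) therefore shows the
test machinery is internally consistent, not that real market runs are
geometric: real series have serial dependence, volatility clustering, and
possibly drifting $\theta$, none of which the generator emulates. Power
against specific alternatives is deliberately out of scope.

## Limitations

* The asymptotic tables assume the MLE $1/\bar X$; other estimators would
  need a different covariance correction.
* The confidence interval for $\theta$ is a delta-method (Wald) interval,
  $\hat\theta \pm z_{(1+\gamma)/2}\sqrt{\hat\theta^2(1-\hat\theta)/n}$,
  from $\mathrm{Var}(\bar X) = (1-\theta)/(n\theta^2)$ — reported as an
  assumption: it reproduces the published market intervals to three
  decimals, but the original construction is not documented.
* Only the one-parameter geometric family is covered; multi-parameter
  corrections and other discrete families are out of scope.
* Brackets require $\hat\theta$ inside the table grid (0.05–0.95); outside
  it the package falls back to the continuous path with a warning.
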