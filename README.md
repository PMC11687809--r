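# geomgof

Goodness-of-fit tests for the geometric distribution when the success
probability is **estimated from the data** — discrete analogues of the
Watson and Anderson-Darling statistics, with their asymptotic null
distributions computed exactly rather than looked up.

## Who this is for

Anyone modelling counts of "trials until first success" — run lengths of
consecutive up/down days in a price series, streak durations, inter-event
trial counts — who wants a calibrated answer to *"is this sample
geometric?"* rather than an eyeballed histogram. The motivating
application is daily price runs of market indices, where the geometric
null with θ ≈ 0.5 corresponds to direction changes behaving like fair
coin flips.

## The statistics

For a sample of positive integers with cell counts *o*₁.. *o*ₖ (*k* the
last non-empty cell), geometric pmf *pᵢ*(θ) = (1−θ)^(i−1) θ, CDF
*Hᵢ* = 1−(1−θ)^i, MLE θ̂ = 1/x̄, and cumulative deviations
*Zⱼ* = Σᵢ≤ⱼ (*oᵢ* − *n pᵢ*(θ̂)):

* Watson:   W²(θ̂) = n⁻¹ Σᵢ Zᵢ² pᵢ(θ̂)
* Anderson-Darling:  A²(θ̂) = n⁻¹ Σᵢ Zᵢ² pᵢ(θ̂) / (Hᵢ(1−Hᵢ))

Both are quadratic forms Zᵀ V Z/n whose null law converges to
Σ λᵢ νᵢ², with νᵢ i.i.d. standard normal and λᵢ the eigenvalues of
V^½ Σ̂ V^½, where Σ̂ = R(D − PPᵀ − bbᵀ/(bᵀD⁻¹b))Rᵀ is the partial-sum
covariance corrected for maximum-likelihood estimation of θ (b the score
vector dpⱼ/dθ). The package builds these spectra, evaluates tail
probabilities of Σ λᵢ νᵢ² by characteristic-function inversion,
regenerates the asymptotic critical-value tables, and cross-checks
everything by Monte Carlo.

## Worked example

The packaged fixture `market_runs()` holds published run-length counts
for four indices (2015–2022). Testing the NASDAQ column:

```r
library(geomgof)
runs <- market_runs()
fit <- gof_test(data.frame(value = runs$length, count = runs$nasdaq))
fit
#> Geometric goodness-of-fit test (estimated theta)
#>   n = 1032   x_bar = 1.952   theta_hat = 0.512   95% CI [0.491, 0.534]
#>   W2 = 0.060   0.25 < p < 0.50   p = 0.453   no rejection at alpha = 0.05
#>   A2 = 0.314   p > 0.50   p = 0.502   no rejection at alpha = 0.05
```

Reading this: 1032 runs averaging 1.952 days give θ̂ = 0.512 — a 51.2%
chance the streak ends each day, indistinguishable from a fair coin.
Neither statistic comes close to its 5% critical value, so the geometric
model is not rejected; the bracketed p-values mirror table-based
reporting, while `p = …` is the exact asymptotic tail probability at θ̂.
Rectangular views and a diagnostic plot:

```r
tidy(fit)     # one row per statistic: value, bracket, p, critical value
glance(fit)   # n, x_bar, theta_hat, CI
autoplot(fit) # observed vs fitted frequencies
```

Other entry points: `critical_value_table()` regenerates the asymptotic
percentage-point grids (`default_critical_values()` is the shipped copy);
`simulate_statistics()` / `empirical_percentage_points()` produce
finite-sample null quantiles; `runs_from_series()` turns a raw numeric
series into run lengths; `wchi2_tail()` / `wchi2_quantile()` expose the
weighted-chi-square distribution machinery directly. A thin CLI over the
same functions lives at `inst/cli/geomgof.R` (subcommands `test`,
`tables`, `simulate`, `runs`).

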