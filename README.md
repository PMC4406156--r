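# mvnmix

Exact multivariate formulations of the N-mixture model for replicated
count surveys, with diagnostics for infinite abundance estimates.

Ecologists estimate animal abundance from counts $y_{it}$ made at $S$
sites over $T$ repeat visits, without marking individuals: site abundance
$N_i$ is a latent draw from a mixing distribution (Poisson,
negative-binomial, or zero-inflated Poisson with mean $\lambda$) and each
count is a binomial thinning $y_{it} \mid N_i \sim \mathrm{Binomial}(N_i,
p)$ with detection probability $p$. The classical likelihood truncates an
infinite sum over $N$ at a bound $K$ — and a careless default $K$ biases
$\hat\lambda$ downward. This package instead evaluates the likelihood
*exactly*: partitioning individuals by the subset of visits on which they
were detected shows the Poisson N-mixture model is a multivariate Poisson
distribution with subset rates $\theta_s = \lambda\, p^{|s|}
(1-p)^{T-|s|}$, and gamma mixing gives a closed-form multivariate
negative binomial. No $K$ is needed.

The second theme is pathology detection. When detection is poor and
visits few, the likelihood can be maximized on the boundary $\lambda \to
\infty$, $p \to 0$ with $p\lambda$ fixed — the data then contain no finite
abundance estimate, and optimizers silently return arbitrarily large
numbers. Two sample-moment diagnostics predict this before fitting:

* `D1 = m11 - m1^2` (intraclass covariance of counts across visits;
  non-positive values predict an infinite Poisson MLE), and
* `D2 = m1 - m2 + m11` (equals `m1 * p_hat` for the method-of-moments
  `p_hat`; non-positive values predict an infinite moment estimate of
  `lambda` under negative-binomial mixing),

where `m1`, `m2`, `m11` are the mean count, mean squared count, and mean
pairwise cross-product. Closed-form method-of-moments estimators provide
starting values for maximum likelihood, and the fitter explicitly reports
boundary (infinite-abundance) solutions instead of a large finite number.

## Worked example

```r
library(mvnmix)

# a healthy design: 100 sites, 3 visits, lambda = 5, p = 0.4
y <- simulate_counts(S = 100, T = 3, lambda = 5, p = 0.4, seed = 1)
diagnose(y)
#> N-mixture moment diagnostics
#>   D1 (covariance)   = 0.676656  [positive]
#>   D2 (moment p-hat) = 0.79  [positive]
#>   both diagnostics positive: finite estimates expected

fit_nmix(y, family = "poisson")
#> poisson N-mixture fit (multivariate formulation)
#>   lambda = 5.067, p = 0.394
#>   loglik = -483.7870, converged = TRUE, iterations = 78
```

Both diagnostics are positive, and the exact multivariate fit recovers
the generating values ($\hat\lambda = 5.07$ against 5, $\hat p = 0.39$
against 0.4). Contrast a risky design — 20 sites, two visits, $p = 0.1$:

```r
sparse <- simulate_counts(S = 20, T = 2, lambda = 2, p = 0.1, seed = 1)
diagnose(sparse)
#> N-mixture moment diagnostics
#>   D1 (covariance)   = -0.0225  [non-positive]
#>   D2 (moment p-hat) = 0  [non-positive]
#>   covariance diagnostic non-positive: expect an infinite Poisson abundance MLE

fit_nmix(sparse, family = "poisson")
#> poisson N-mixture fit (multivariate formulation)
#>   lambda = 2.217e+06 (boundary: infinite), p = 6.766e-08
#>   loglik = -17.3827, converged = FALSE, iterations = 65
```

The negative covariance diagnostic correctly predicts the outcome: the
likelihood is flat along $p\lambda \approx$ constant, the estimate races
to the boundary, and the fit is flagged `boundary: infinite` rather than
reported as a (meaningless) large number. About half of all datasets
simulated under this design behave this way.

A command-line wrapper ships in `inst/cli/mvnmix`
(`mvnmix fit|diagnose|simulate|experiment ...`), writing JSON reports and
tidy CSV study results.

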