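---
title: "Exact multivariate formulations of the N-mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact multivariate formulations of the N-mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvnmix)
```

## The model

Replicated count surveys record $y_{it}$, the number of individuals counted
at site $i = 1, \dots, S$ on visit $t = 1, \dots, T$, with the population
closed over the survey. The N-mixture model treats the site abundances
$N_i$ as independent draws from a mixing distribution $f$ and the counts as
conditionally independent binomial thinnings,

$$ y_{it} \mid N_i \sim \mathrm{Binomial}(N_i, p), $$

with a common per-individual, per-visit detection probability $p$. The
classical likelihood marginalizes $N_i$ by an infinite sum, truncated in
practice at a bound $K$:

$$ L(\lambda, p) = \prod_{i=1}^{S} \sum_{N = \max_t y_{it}}^{K}
   f(N; \lambda) \prod_{t=1}^{T} \binom{N}{y_{it}} p^{y_{it}}
   (1-p)^{N - y_{it}}. $$

Three mixing families are supported, all parameterized so that $\lambda$ is
the mean abundance:

* **Poisson** with mean $\lambda$;
* **negative binomial** (NB-2): the Poisson mean is gamma with shape $a$ and
  rate $b = a/\lambda$, so $\mathrm{Var}(N) = \lambda + \lambda^2/a$ and the
  coefficient of variation of the Poisson mean is $1/\sqrt{a}$;
* **zero-inflated Poisson**: $N_i = 0$ with probability $\psi$, otherwise
  Poisson($\lambda$). The published analyses fit a ZIP without printing its
  parameterization; this standard two-part form is the package's choice.

## The exact multivariate formulation

Individuals at a site can be partitioned by the *subset of visits* on which
they were detected. For each non-empty subset $s \subseteq \{1,\dots,T\}$
let $n_s$ count the individuals seen exactly on the visits in $s$; each
individual falls in subset $s$ with probability
$w_s = p^{|s|}(1-p)^{T-|s|}$. Under Poisson abundance the $n_s$ are
independent Poisson with rates $\theta_s = \lambda w_s$, and the counts
$y_t = \sum_{s \ni t} n_s$ follow a multivariate Poisson distribution whose
pmf is an exact finite sum over the configuration set
$A_y = \{ n \ge 0 : \sum_{s \ni t} n_s = y_t \;\forall t \}$:

$$ \Pr(y) = \sum_{n \in A_y} \prod_s \frac{\theta_s^{n_s}
   e^{-\theta_s}}{n_s!}. $$

This is *identical* to the classical likelihood with $K = \infty$ but needs
no truncation constant. Gamma mixing integrates in closed form to the
multivariate negative binomial,

$$ \Pr(y) = \sum_{n \in A_y} \left( \prod_s \frac{w_s^{n_s}}{n_s!} \right)
   \frac{\Gamma(a + M)}{\Gamma(a)} \frac{b^a}{(b + W)^{a + M}},
   \qquad M = \sum_s n_s, \quad W = 1 - (1-p)^T, $$

which recovers the thinned negative binomial at $T = 1$ and the
multivariate Poisson as $a \to \infty$. Both identities are verified in the
test suite against brute-force mixture sums.

`enumerate_configs()` builds $A_y$ by a depth-first search over subsets in
a canonical order (size ascending, then lexicographic), keeping
per-occasion remaining budgets and pruning any branch that strands a
positive budget. The published description promises only "efficient
construction", so the DFS-with-budgets scheme is this package's design; it
is validated against an exhaustive grid-scan oracle. The configuration
count grows combinatorially with $T$ and the counts — with $2^T - 1$
latent dimensions the exact formulation is intended for the small-$T$
designs (two or three visits) where infinite estimates are an actual
hazard; `max_configs` guards the enumeration and larger designs use the
truncated formulation, which costs $O(K)$ per site regardless of $T$.

All pmfs are evaluated in log space with log-sum-exp over configurations
($\Gamma(a+M)$ and the factorials overflow quickly otherwise); a site
probability that still underflows to zero raises an error rather than
silently returning $-\infty$.

## Choosing the truncation bound

With a fixed $K$ too small, the likelihood at the boundary cannot express
large abundances and $\hat\lambda$ piles up just below the ceiling — the
sampling distribution develops a spurious upper mode whose location grows
with $K$ (`run_k_sensitivity()` reproduces this). In `auto` mode the
package instead selects the smallest $K$ with upper-tail probability
$\Pr(N > K) < \varepsilon$ under the current mixing estimate, floored at
the largest observed count and refreshed from the current $\lambda$ on
every likelihood evaluation during optimization. The published account
does not print its threshold; the default here is $\varepsilon = 10^{-5}$
(configurable), which puts the truncation error well below the optimizer
tolerance for typical datasets — the dataset-level error scales roughly as
$S\varepsilon$, so reproducing log-likelihoods to $10^{-6}$ in the tests
uses $\varepsilon = 10^{-8}$. The tail rule uses each family's own cdf,
the natural generalization of the Poisson-case rule. A hard cap
($K \le 10^6$) converts a runaway $\lambda$ into a diagnosable error.

## Moments, diagnostics, and infinite estimates

Writing $m_1$ for the grand mean count, $m_2$ for the mean squared count
and $m_{11}$ for the average over unordered visit pairs of the mean
cross-product, the mixed-Poisson model (mixing mean $\mu$, mixing variance
$\sigma^2$) implies

$$ E(Y) = p\mu, \qquad E(Y^2) = p(1-p)\mu + p^2(\mu + \sigma^2 + \mu^2),
   \qquad E(Y_t Y_u) = p^2 (\mu + \sigma^2 + \mu^2). $$

Solving these gives closed-form method-of-moments estimators
($\hat p = (m_1 - m_2 + m_{11})/m_1$, $\hat\lambda = m_1/\hat p$,
$\hat a = \hat\lambda^2/\hat\sigma^2$) and two diagnostics:

* **D1** $= m_{11} - m_1^2$, the intraclass covariance of counts across
  visits (pooled mean, since all visits share $E(Y) = p\mu$). Its
  population value $p^2(\mu + \sigma^2)$ is strictly positive, and a
  non-positive sample value indicates that the likelihood prefers
  $p \to 0$, $\lambda \to \infty$ with $p\lambda$ fixed: for the Poisson
  family a non-positive D1 predicts an infinite abundance MLE almost
  perfectly (the EPN/EPD correspondence).
* **D2** $= m_1 - m_2 + m_{11} = m_1 \hat p$: its positivity is exactly
  what makes the moment estimate of $p$ positive and the moment estimate
  of $\lambda$ finite — the additional diagnostic needed under
  negative-binomial mixing. (The upper bound $\hat p \le 1$ is a
  Cauchy–Schwarz consequence and never informative.)

Two sign conventions coexist deliberately. The *prediction* flags in
`diagnose()` treat an exact zero as a failure (non-positive convention): a
sparse 0/1 dataset with no co-detections has $m_2 = m_1$ and $D_2 = m_{11}
= 0$ exactly, and such data carry no information to separate $p$ from
$\lambda$. The *study runners* (`run_nb_diag_study()`) count strictly
negative values by default, because that is the convention under which the
published negative-binomial study proportions reproduce; the tie mass is
substantial precisely in the sparse scenarios. Sample correlations (used
by the correlation-form MOM for the Poisson family, where the population
correlation between visits equals $p$) are scale-invariant to the
$1/S$-versus-$1/(S-1)$ choice; the cross-moment solver necessarily uses
the $1/S$ moments shown above.

## Fitting and the boundary rule

`fit_nmix()` maximizes either formulation over $(\log\lambda,
\mathrm{logit}\,p, \log a, \mathrm{logit}\,\psi)$ with Nelder–Mead
(`reltol = 1e-8`, 500 iterations per round), starting from the MOM
estimates when valid and from $(p = 0.5, \lambda = m_1/0.5, a = 1)$
otherwise. Because the infinite-abundance ridge is flat, a single
optimizer run can terminate prematurely at an arbitrarily large but
finite $\hat\lambda$; the fit therefore restarts the simplex from its own
endpoint (up to `max_rounds`) until $\hat\lambda$ moves by less than 1%
between rounds, and declares `boundary_infinite` when $\hat\lambda$
exceeds `infinite_threshold` ($10^3$ by default — the sampling
distribution of $\hat\lambda$ is strongly bimodal, so any large cutoff
separates the modes; the published operational cutoff is not stated) or
when the rounds end with $\hat\lambda$ still growing monotonically. Three
jittered, seeded restarts back up outright optimizer failures. Under this
rule essentially *all* replicates whose two diagnostics are negative give
infinite negative-binomial estimates (the corresponding published summary,
0.921, is consistent with an optimizer occasionally stopping below the
cutoff — a hazard the original account itself emphasizes).

## The simulation engine and what it does (not) emulate

`simulate_counts()` draws $N_i$ from the chosen family and thins
binomially — exactly the generating model above, reproducible from a seed
without touching the caller's RNG state. The study runners derive
per-scenario, per-replicate child seeds from one root seed
(counter-based), so results are invariant to execution order. The study
conditions are frozen as the generator defaults: the Poisson study grid is
$S = 20$ sites with $T \in \{2, 3, 4\}$, $\lambda \in \{2, 5, 10\}$,
$p \in \{0.10, 0.25\}$ at 1000 replicates; the negative-binomial grid
additionally crosses gamma shape $a \in \{1.25, 5\}$ (CV $\approx 0.89,
0.45$) with $T \in \{2, 3\}$. The conditional-infinite summaries in the
test suite run at 200–300 replicates per scenario with the
negative-binomial fits restricted to the qualifying sign groups (a seeded
25-fit subsample per scenario for the large both-positive group), keeping
the whole suite within desk-scale run times; the vignette-level claims are
exactly the quantities those tests and `scripts/acceptance.R` compute.

The generator emulates balanced designs with homogeneous $\lambda$ and
$p$ and no temporal trend. Real surveys violate all three (site and visit
covariates, open populations, observer effects), so passing tests
demonstrate correctness of the estimators and diagnostics under the
stated model, not robustness of the model itself to field realities.

## Numerical choices and known limitations

* Occasions are labelled $1..T$ externally; subset order is size-then-lex
  and deterministic, so $\theta_s$ indices are stable across modules.
* Degenerate inputs fail loudly: all-zero matrices (no identifiable
  parameters), single-visit data (only $p\lambda$ estimable; reported as
  such with a non-identifiability flag), ragged or negative input.
* The exact enumeration is exponential in $T$; use the truncated
  formulation for $T \gtrsim 4$ with non-trivial counts.
* Standard errors and covariate models are out of scope; the moment
  estimators serve as diagnostics and starting values rather than a
  complete inference method.
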