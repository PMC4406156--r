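test_that("multivariate Poisson pmf matches closed forms at T = 2", {
  # zero counts: exp(-lambda * (1 - (1-p)^2))
  expect_equal(dmvpois(c(0, 0), 1, 0.5), exp(-0.75))
  # single latent configuration (1,0,0): theta_1 * exp(-sum theta)
  expect_equal(dmvpois(c(1, 0), 1, 0.5), 0.25 * exp(-0.75))
  # two-term closed form at y = (1,1)
  expect_equal(dbivpois(1, 1, 1, 0.5), exp(-0.75) * 0.3125)
  expect_equal(dbivpois(0, 0, 2, 0.3), exp(-2 * (1 - 0.7^2)))
})

test_that("bivariate closed form and general subset-decomposition pmf are identical", {
  for (lambda in c(0.5, 2, 7)) for (p in c(0.1, 0.4, 0.8)) {
    for (y1 in 0:4) for (y2 in 0:4) {
      expect_equal(dbivpois(y1, y2, lambda, p),
                   dmvpois(c(y1, y2), lambda, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("multivariate pmfs match the brute-force truncated mixture oracle", {
  # Poisson, T = 3
  expect_equal(dmvpois(c(2, 1, 1), 2, 0.25),
               oracle_pois_pmf(c(2, 1, 1), 2, 0.25, K = 500),
               tolerance = 1e-12)
  ys <- list(c(0L, 0L), c(1L, 0L), c(2L, 3L), c(4L, 4L), c(0L, 5L))
  for (y in ys) {
    expect_equal(dmvpois(y, 3, 0.35), oracle_pois_pmf(y, 3, 0.35),
                 tolerance = 1e-10)
    expect_equal(dmvnbinom(y, 3, 2, 0.35), oracle_nb_pmf(y, 3, 2, 0.35),
                 tolerance = 1e-10)
  }
  # negative binomial, spec-level case
  expect_equal(dmvnbinom(c(1, 1), 2, 5, 0.25),
               oracle_nb_pmf(c(1, 1), 2, 5, 0.25), tolerance = 1e-12)
})

test_that("single-visit negative binomial reduces to the thinned NB closed form", {
  for (y in 0:5) {
    lambda <- 2; a <- 5; p <- 0.25; b <- a / lambda
    closed <- (p^y / factorial(y)) * gamma(a + y) / gamma(a) *
      b^a / (b + p)^(a + y)
    expect_equal(dmvnbinom(y, lambda, a, p), closed, tolerance = 1e-12)
  }
})

test_that("negative binomial converges to Poisson as the shape grows", {
  for (lambda in c(1, 5)) for (p in c(0.2, 0.5)) {
    for (y in list(c(0L, 0L), c(2L, 1L), c(3L, 3L))) {
      nb <- dmvnbinom(y, lambda, a = 1e6, p)
      po <- dmvpois(y, lambda, p)
      expect_lt(abs(nb - po) / po, 1e-4)
    }
  }
})

test_that("zero-inflated Poisson pmf is the stated two-part mixture", {
  # psi = 0 degenerates to the Poisson pmf
  expect_equal(dmvzip(c(1, 2), 2, 0.3, psi = 0), dmvpois(c(1, 2), 2, 0.3))
  # zero vector carries the point mass
  expect_equal(dmvzip(c(0, 0), 1, 0.5, psi = 0.3),
               0.3 + 0.7 * exp(-0.75))
  # non-zero y kills the point mass
  expect_equal(dmvzip(c(1, 1), 1, 0.5, psi = 0.3),
               0.7 * dbivpois(1, 1, 1, 0.5))
})

test_that("T = 2 pmf mass sums to one up to the analytic tail bound", {
  for (lambda in c(1, 4)) for (p in c(0.2, 0.6)) {
    ymax <- 30
    tot <- sum(outer(0:ymax, 0:ymax,
                     Vectorize(function(a, b) dmvpois(c(a, b), lambda, p))))
    # counts are bounded by N: P(any Y > ymax) <= 2 P(Poisson(lambda) > ymax)
    expect_gte(tot, 1 - 2 * ppois(ymax, lambda, lower.tail = FALSE))
    expect_lte(tot, 1 + 1e-12)
    totnb <- sum(outer(0:ymax, 0:ymax,
                       Vectorize(function(a, b) dmvnbinom(c(a, b), lambda, 2, p))))
    expect_gte(totnb, 1 - 2 * pnbinom(ymax, size = 2, mu = lambda,
                                      lower.tail = FALSE))
    expect_lte(totnb, 1 + 1e-12)
  }
})

test_that("counts become independent as p tends to zero at fixed p * lambda", {
  mu <- 0.5  # fixed expected count per visit
  for (p in c(0.2, 0.02, 0.002)) {
    lambda <- mu / p
    # dependence rate for the pair subset vanishes relative to singletons
    w <- thinning_weights(subset_system(2), p)
    expect_equal(w[3] / w[1], p / (1 - p))
  }
  # at small p the joint pmf factorizes into thinned Poisson margins
  p <- 1e-4; lambda <- mu / p
  joint <- dmvpois(c(1, 2), lambda, p)
  indep <- dpois(1, mu) * dpois(2, mu)
  expect_lt(abs(joint - indep) / indep, 1e-3)
})

test_that("dataset log-likelihood is the sum of per-site log masses", {
  pars <- nmix_params("poisson", lambda = 1, p = 0.5)
  expect_equal(loglik_mv(rbind(c(0, 0)), pars), -0.75)
  y <- matrix(rep(c(1L, 2L), each = 7), nrow = 7)
  expect_equal(loglik_mv(y, pars), 7 * dmvpois(c(1, 2), 1, 0.5, log = TRUE))
})
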