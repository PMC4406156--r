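test_that("Poisson MLE recovers the generating parameters", {
  set.seed(201)
  est <- t(vapply(1:6, function(i) {
    y <- count_matrix(sim_counts_raw(200, 3, 5, 0.5))
    f <- fit_nmix(y, "poisson")
    expect_true(f$converged)
    expect_false(f$boundary_infinite)
    c(f$estimates$lambda, f$estimates$p)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 5), 3 * sd(est[, 1]) / sqrt(6))
  expect_lt(abs(mean(est[, 2]) - 0.5), 3 * sd(est[, 2]) / sqrt(6))
})

test_that("multivariate and truncated formulations give the same maximum", {
  y <- simulate_counts(80, 3, 4, 0.4, seed = 31)
  f1 <- fit_nmix(y, "poisson", formulation = "multivariate")
  f2 <- fit_nmix(y, "poisson", formulation = "truncated",
                 policy = truncation_policy(epsilon = 1e-12))
  expect_lt(abs(f1$loglik - f2$loglik), 1e-5)
  expect_lt(abs(f1$estimates$lambda - f2$estimates$lambda) /
              f1$estimates$lambda, 1e-3)
  expect_lt(abs(f1$estimates$p - f2$estimates$p) / f1$estimates$p, 1e-3)
  expect_false(is.na(f2$K_used))
})

test_that("a negative covariance diagnostic leads to a boundary fit", {
  found <- 0L
  for (s in 1:30) {
    y <- simulate_counts(20, 2, 2, 0.1, seed = s)
    if (sum(y) == 0 || cov_diagnostic(y) > 0) next
    found <- found + 1L
    f <- fit_nmix(y, "poisson")
    expect_true(f$boundary_infinite)
    expect_gt(f$estimates$lambda, f$infinite_threshold)
    if (found >= 3L) break
  }
  expect_gte(found, 3L)
})

test_that("MOM estimates seed the optimizer when valid", {
  y <- simulate_counts(150, 3, 5, 0.5, seed = 37)
  f <- fit_nmix(y, "poisson")
  expect_true(f$start_mom)
  expect_equal(f$start$p, mom_poisson(y)$p_hat, tolerance = 1e-10)
  # invalid MOM falls back to the neutral start and flags it
  y2 <- simulate_counts(20, 2, 2, 0.1, seed = 4)  # sparse, D1 <= 0
  if (cov_diagnostic(y2) <= 0) {
    f2 <- fit_nmix(y2, "poisson")
    expect_false(f2$start_mom)
    expect_equal(f2$start$p, 0.5)
  }
})

test_that("ZIP fits recover the zero-inflation mass", {
  y <- simulate_counts(600, 3, 5, 0.4, "zip", psi = 0.3, seed = 41)
  f <- fit_nmix(y, "zip")
  expect_false(f$boundary_infinite)
  expect_lt(abs(f$estimates$psi - 0.3), 0.1)
  expect_lt(abs(f$estimates$lambda - 5), 0.75)
})

test_that("single-visit data estimate only the product p * lambda", {
  y <- simulate_counts(500, 1, 5, 0.4, seed = 43)
  f <- fit_nmix(y, "poisson")
  expect_false(f$identifiable)
  expect_lt(abs(f$estimates$product - 2), 0.2)
  expect_true(is.na(f$estimates$lambda))
})

test_that("all-zero counts are rejected", {
  expect_error(fit_nmix(matrix(0L, 10, 2), "poisson"), "identifiable")
})

test_that("overdispersed data can be Poisson-finite but negative-binomial-infinite", {
  # strongly clumped abundances: the covariance diagnostic is positive (the
  # Poisson abundance MLE is finite) while the second diagnostic is negative
  # and the negative-binomial likelihood climbs the infinite-abundance ridge
  y <- simulate_counts(50, 3, 2, 0.15, "negbin", a = 0.5, seed = 2002)
  expect_gt(cov_diagnostic(y), 0)
  expect_lt(nb_diagnostic(y), 0)
  fp <- fit_nmix(y, "poisson")
  fn <- fit_nmix(y, "negbin")
  expect_false(fp$boundary_infinite)
  expect_true(fn$boundary_infinite)
  expect_gt(fn$loglik, fp$loglik)  # the NB boundary fit still fits better
})

test_that("profile likelihood is flat-increasing on diagnostic-negative data", {
  for (s in 1:30) {
    y <- simulate_counts(20, 2, 2, 0.1, seed = s)
    if (sum(y) > 0 && cov_diagnostic(y) <= 0) break
  }
  pr <- profile_lambda(y, "poisson", c(1e2, 1e3, 1e4))
  expect_true(all(diff(pr) >= -1e-8))
})

test_that("profile likelihood has an interior maximum on well-behaved data", {
  y <- simulate_counts(100, 3, 5, 0.5, seed = 3)
  grid <- c(2, 5, 8, 50)
  pr <- profile_lambda(y, "poisson", grid)
  expect_gt(max(pr[2], pr[3]), pr[1])
  expect_gt(max(pr[2], pr[3]), pr[4])
  # a single-lambda grid equals the corresponding fixed-lambda maximum
  pr1 <- profile_lambda(y, "poisson", 5)
  expect_equal(pr1, pr[2])
})
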