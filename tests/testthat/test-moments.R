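test_that("sample moments follow their definitions", {
  m <- sample_moments(rbind(c(1, 2), c(3, 4)))
  expect_equal(m$m1, 2.5)
  expect_equal(m$m2, 7.5)
  expect_equal(m$m11, 7)

  z <- sample_moments(matrix(0L, 4, 3))
  expect_equal(unlist(z), c(m1 = 0, m2 = 0, m11 = 0))

  # T = 3: m11 averages the three pairwise products
  m3 <- sample_moments(rbind(c(1, 2, 3)))
  expect_equal(m3$m11, (1 * 2 + 1 * 3 + 2 * 3) / 3)

  expect_error(sample_moments(matrix(1L, 3, 1)), "two occasions")
})

test_that("covariance diagnostics follow their closed forms", {
  expect_equal(cov_diagnostic(rbind(c(1, 1), c(1, 1))), 0)
  expect_equal(cov_diagnostic(rbind(c(2, 0), c(0, 2))), -1)
  expect_equal(nb_diagnostic(rbind(c(1, 2), c(3, 4))), 2.5 - 7.5 + 7)
  # equal columns: m2 = m11 so D2 = m1
  y <- cbind(c(0L, 2L, 5L), c(0L, 2L, 5L))
  expect_equal(nb_diagnostic(y), mean(y))
  # the T = 2 specialization of the general pairwise-average form is exact
  y2 <- count_matrix(rbind(c(3, 1), c(0, 2), c(4, 4)))
  expect_equal(cov_diagnostic(y2),
               mean(y2[, 1] * y2[, 2]) - mean(y2)^2)
})

test_that("D1 estimates p^2 * lambda under Poisson mixing", {
  set.seed(101)
  reps <- vapply(1:60, function(i)
    cov_diagnostic(sim_counts_raw(4000, 2, 5, 0.3)), numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.3^2 * 5), 3 * se + 1e-12)
})

test_that("D2 / m1 is a consistent estimator of p", {
  set.seed(102)
  p <- 0.35; lambda <- 4
  reps <- vapply(1:40, function(i) {
    y <- sim_counts_raw(5000, 2, lambda, p)
    nb_diagnostic(y) / mean(y)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - p), 3 * se)
})

test_that("Cauchy-Schwarz keeps the moment p-hat at most one", {
  set.seed(103)
  for (i in 1:50) {
    y <- sim_counts_raw(30, sample(2:4, 1), runif(1, 0.5, 8), runif(1, 0.05, 0.9))
    m <- sample_moments(count_matrix(y))
    expect_gte(m$m2, m$m11 - 1e-12)
  }
})

test_that("correlation-based MOM handles the degenerate sign cases", {
  # perfectly correlated columns: p-hat = 1, lambda-hat = mean
  y <- cbind(c(1L, 3L, 5L), c(1L, 3L, 5L))
  m <- mom_poisson(y)
  expect_true(m$valid)
  expect_equal(m$p_hat, 1)
  expect_equal(m$lambda_hat, 3)
  # anti-correlated toy: infinite prediction
  m2 <- mom_poisson(rbind(c(2, 0), c(0, 2)))
  expect_false(m2$valid)
  expect_equal(m2$p_hat, -1)
  expect_identical(m2$lambda_hat, Inf)
  # zero variance in one occasion: correlation undefined
  m3 <- mom_poisson(cbind(c(1L, 1L), c(0L, 2L)))
  expect_false(m3$valid)
  expect_match(m3$reason, "variance")
})

test_that("correlation-based MOM recovers p and lambda under Poisson mixing", {
  set.seed(104)
  p <- 0.25; lambda <- 5
  est <- t(vapply(1:30, function(i) {
    m <- mom_poisson(sim_counts_raw(10000, 2, lambda, p))
    c(m$p_hat, m$lambda_hat)
  }, numeric(2)))
  # population correlation of the two counts equals p for Poisson mixing
  expect_lt(abs(mean(est[, 1]) - p), 3 * sd(est[, 1]) / sqrt(30))
  expect_lt(abs(mean(est[, 2]) - lambda), 3 * sd(est[, 2]) / sqrt(30))
})

test_that("cross-moment MOM solves the worked example and flags failures", {
  m <- mom_mixed_poisson(rbind(c(1, 2), c(3, 4)))
  expect_equal(m$p_hat, 0.8)
  expect_equal(m$lambda_hat, 3.125)
  expect_lt(m$sigma2_hat, 0)
  expect_true(is.na(m$a_hat))  # Poisson-compatible: shape not estimable
  expect_true(m$valid)
  expect_match(m$reason, "Poisson-compatible")

  # D2 <= 0 forces an infinite lambda estimate
  bad <- mom_mixed_poisson(rbind(c(2, 0), c(0, 2)))
  expect_false(bad$valid)
  expect_identical(bad$lambda_hat, Inf)

  expect_error(mom_mixed_poisson(matrix(0L, 3, 1)), "two occasions")
  nd <- mom_mixed_poisson(matrix(0L, 3, 2))
  expect_false(nd$valid)
  expect_match(nd$reason, "no detections")
})

test_that("cross-moment MOM recovers negative-binomial parameters", {
  set.seed(105)
  lambda <- 5; a <- 2; p <- 0.4
  est <- t(vapply(1:25, function(i) {
    m <- mom_mixed_poisson(sim_counts_raw(20000, 3, lambda, p, "negbin", a = a))
    c(m$p_hat, m$lambda_hat, m$a_hat)
  }, numeric(3)))
  for (j in 1:3) {
    truth <- c(p, lambda, a)[j]
    expect_lt(abs(mean(est[, j]) - truth), 3 * sd(est[, j]) / sqrt(nrow(est)))
  }
})

test_that("moment estimator bias shrinks as the number of sites grows", {
  set.seed(106)
  bias <- vapply(c(100, 1000, 10000), function(S) {
    est <- vapply(1:20, function(i)
      mom_mixed_poisson(sim_counts_raw(S, 2, 4, 0.4))$p_hat, numeric(1))
    abs(mean(est, na.rm = TRUE) - 0.4)
  }, numeric(1))
  expect_lt(bias[3], bias[1])
})

test_that("diagnose combines the two diagnostics into sign flags", {
  d <- diagnose(rbind(c(2, 0), c(0, 2)))
  expect_equal(d$D1, -1)
  expect_true(d$d1_negative)
  expect_true(d$predicted_infinite_poisson)
  d2 <- diagnose(rbind(c(1, 2), c(3, 4)))
  expect_false(d2$d1_negative)
  expect_false(d2$d2_negative)
  expect_match(d2$recommendation, "finite")
})
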