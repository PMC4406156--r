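#' Sample moments of a count matrix
#'
#' The three sample moments that drive the diagnostics and the
#' method-of-moments estimators: `m1`, the grand mean of all counts; `m2`,
#' the mean of the squared counts; and `m11`, the average over the
#' T(T-1)/2 unordered occasion pairs of the mean cross-product
#' y_it * y_iu. Their population counterparts under a mixed-Poisson
#' N-mixture model with mixing mean mu and mixing variance sigma^2 are
#' E(Y) = p mu, E(Y^2) = p(1-p) mu + p^2 (mu + sigma^2 + mu^2), and
#' E(Y_t Y_u) = p^2 (mu + sigma^2 + mu^2).
#'
#' @param counts a [count_matrix()] (or coercible); needs T >= 2.
#' @return a list with `m1`, `m2`, `m11`.
#' @export
sample_moments <- function(counts) {
  counts <- count_matrix(counts)
  if (ncol(counts) < 2L)
    stop("moments m11 require at least two occasions", call. = FALSE)
  pairs <- utils::combn(ncol(counts), 2L)
  m11 <- mean(apply(pairs, 2L, function(tu)
    mean(counts[, tu[1]] * counts[, tu[2]])))
  list(m1 = mean(counts), m2 = mean(counts^2), m11 = m11)
}

#' Covariance diagnostics for infinite abundance estimates
#'
#' `cov_diagnostic()` returns D1 = m11 - m1^2, the intraclass sample
#' covariance of counts across occasions (pooled mean, since every occasion
#' shares E(Y) = p mu). Its population value is p^2 (mu + sigma^2) > 0, so
#' a non-positive sample value signals that the likelihood prefers p -> 0
#' with lambda -> infinity: for the Poisson family, D1 <= 0 predicts an
#' infinite abundance MLE. `nb_diagnostic()` returns
#' D2 = m1 - m2 + m11 = m1 * p_hat, the moment condition whose positivity
#' makes the method-of-moments detection probability (and hence the moment
#' estimate of lambda) finite and positive; it is the additional diagnostic
#' for the negative-binomial family.
#'
#' @param counts a [count_matrix()] (or coercible) with T >= 2.
#' @return a single numeric value.
#' @seealso [diagnose()] for the combined report.
#' @export
cov_diagnostic <- function(counts) {
  m <- sample_moments(counts)
  m$m11 - m$m1^2
}

#' @rdname cov_diagnostic
#' @export
nb_diagnostic <- function(counts) {
  m <- sample_moments(counts)
  m$m1 - m$m2 + m$m11
}

#' Diagnostic report on the risk of infinite abundance estimates
#'
#' Evaluates both covariance diagnostics and turns their signs into validity
#' verdicts. Flags use the non-positive convention (a diagnostic exactly
#' zero is a pathological tie -- typically a sparse dataset with no
#' co-detections -- and is treated as a failure). `d1_negative` predicts an
#' infinite Poisson MLE; `d2_negative` predicts an infinite moment estimate
#' of lambda under negative-binomial mixing.
#'
#' @param counts a [count_matrix()] (or coercible) with T >= 2.
#' @return a list of class `"nmix_diag"` with `D1`, `D2`, the sign flags,
#'   and the moment estimates from [mom_mixed_poisson()].
#' @export
diagnose <- function(counts) {
  counts <- count_matrix(counts)
  D1 <- cov_diagnostic(counts)
  D2 <- nb_diagnostic(counts)
  mom <- mom_mixed_poisson(counts)
  structure(list(
    D1 = D1, D2 = D2,
    d1_negative = D1 <= 0,
    d2_negative = D2 <= 0,
    predicted_infinite_poisson = D1 <= 0,
    predicted_infinite_negbin_moments = D2 <= 0,
    moments = sample_moments(counts),
    mom = mom,
    recommendation = if (D1 <= 0)
      "covariance diagnostic non-positive: expect an infinite Poisson abundance MLE"
    else if (D2 <= 0)
      "second diagnostic non-positive: expect an infinite negative-binomial moment estimate"
    else
      "both diagnostics positive: finite estimates expected"
  ), class = "nmix_diag")
}

#' @export
print.nmix_diag <- function(x, ...) {
  cat("N-mixture moment diagnostics\n")
  cat(sprintf("  D1 (covariance)   = %.6g  [%s]\n", x$D1,
              if (x$d1_negative) "non-positive" else "positive"))
  cat(sprintf("  D2 (moment p-hat) = %.6g  [%s]\n", x$D2,
              if (x$d2_negative) "non-positive" else "positive"))
  cat("  ", x$recommendation, "\n", sep = "")
  invisible(x)
}

#' Method-of-moments estimators
#'
#' `mom_poisson()` estimates p by the mean of the sample correlations
#' between counts on different occasions (the population correlation of
#' counts under Poisson mixing equals p), and lambda by the grand mean
#' divided by that estimate. `mom_mixed_poisson()` solves the three moment
#' equations of the mixed-Poisson model in closed form:
#' p_hat = (m1 - m2 + m11) / m1, lambda_hat = m1 / p_hat, mixing variance
#' sigma2_hat = m11 / p_hat^2 - lambda_hat - lambda_hat^2, and gamma shape
#' a_hat = lambda_hat^2 / sigma2_hat. Failures (non-positive p_hat, zero
#' mean, negative sigma2_hat) are flagged, never silently clipped.
#'
#' @param counts a [count_matrix()] (or coercible) with T >= 2.
#' @return a list of class `"nmix_mom"` with entries `p_hat`, `lambda_hat`
#'   (`Inf` when the diagnostic fails), `a_hat` (mixed-Poisson method, `NA`
#'   when the shape is invalid), `sigma2_hat`, `valid`, `method`, `reason`.
#' @export
mom_poisson <- function(counts) {
  counts <- count_matrix(counts)
  if (ncol(counts) < 2L)
    stop("moment estimation requires at least two occasions", call. = FALSE)
  m1 <- mean(counts)
  pairs <- utils::combn(ncol(counts), 2L)
  cors <- apply(pairs, 2L, function(tu) {
    suppressWarnings(stats::cor(counts[, tu[1]], counts[, tu[2]]))
  })
  if (anyNA(cors))
    return(structure(list(p_hat = NA_real_, lambda_hat = NA_real_,
                          a_hat = NULL, valid = FALSE,
                          method = "correlation",
                          reason = "zero variance on some occasion: correlation undefined"),
                     class = "nmix_mom"))
  p_hat <- mean(cors)
  if (p_hat <= 0)
    return(structure(list(p_hat = p_hat, lambda_hat = Inf, a_hat = NULL,
                          valid = FALSE, method = "correlation",
                          reason = "non-positive mean correlation: lambda estimate infinite"),
                     class = "nmix_mom"))
  structure(list(p_hat = min(p_hat, 1), lambda_hat = m1 / min(p_hat, 1),
                 a_hat = NULL, valid = TRUE, method = "correlation",
                 reason = NULL),
            class = "nmix_mom")
}

#' @rdname mom_poisson
#' @export
mom_mixed_poisson <- function(counts) {
  counts <- count_matrix(counts)
  if (ncol(counts) < 2L)
    stop("moment estimation requires at least two occasions", call. = FALSE)
  m <- sample_moments(counts)
  out <- list(p_hat = NA_real_, lambda_hat = NA_real_, a_hat = NA_real_,
              sigma2_hat = NA_real_, valid = FALSE, method = "cross-moment",
              reason = NULL)
  if (m$m1 == 0) {
    out$reason <- "no detections: parameters not estimable"
    return(structure(out, class = "nmix_mom"))
  }
  p_hat <- (m$m1 - m$m2 + m$m11) / m$m1
  out$p_hat <- p_hat
  if (p_hat <= 0) {
    out$lambda_hat <- Inf
    out$reason <- "second diagnostic non-positive: lambda estimate infinite"
    return(structure(out, class = "nmix_mom"))
  }
  p_hat <- min(p_hat, 1)  # Cauchy-Schwarz keeps this at most 1 + rounding
  lambda_hat <- m$m1 / p_hat
  sigma2_hat <- m$m11 / p_hat^2 - lambda_hat - lambda_hat^2
  out$p_hat <- p_hat
  out$lambda_hat <- lambda_hat
  out$sigma2_hat <- sigma2_hat
  if (m$m11 - m$m1^2 <= 0) {
    out$reason <- "covariance diagnostic non-positive"
    return(structure(out, class = "nmix_mom"))
  }
  if (sigma2_hat <= 0) {
    out$a_hat <- NA_real_
    out$valid <- TRUE
    out$reason <- "non-positive mixing variance: Poisson-compatible, shape not estimable"
    return(structure(out, class = "nmix_mom"))
  }
  out$a_hat <- lambda_hat^2 / sigma2_hat
  out$valid <- TRUE
  structure(out, class = "nmix_mom")
}

#' @export
print.nmix_mom <- function(x, ...) {
  cat(sprintf("method-of-moments (%s): p_hat = %.4g, lambda_hat = %.4g",
              x$method, x$p_hat, x$lambda_hat))
  if (!is.null(x$a_hat) && !is.na(x$a_hat)) cat(sprintf(", a_hat = %.4g", x$a_hat))
  cat(sprintf("  [%s]\n", if (x$valid) "valid" else "invalid"))
  if (!is.null(x$reason)) cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}
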