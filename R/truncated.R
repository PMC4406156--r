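#' Truncation policy for the classical N-mixture likelihood
#'
#' The classical likelihood replaces the infinite sum over latent abundance
#' N by a finite sum up to K. `mode = "fixed"` uses the supplied K
#' (useful mainly to study the bias a poor K induces). `mode = "auto"`
#' chooses the smallest K whose upper-tail probability under the current
#' mixing distribution is below `epsilon`, floored at the largest observed
#' count, and refreshes K from the current lambda on every likelihood
#' evaluation during optimization.
#'
#' @param mode `"auto"` or `"fixed"`.
#' @param K upper bound (fixed mode).
#' @param epsilon upper-tail probability threshold (auto mode), in (0, 0.1].
#' @param K_cap hard cap on K; exceeding it is an error, so a runaway
#'   lambda cannot allocate unbounded sums.
#' @return a list of class `"truncation_policy"`.
#' @export
truncation_policy <- function(mode = c("auto", "fixed"), K = NULL,
                              epsilon = 1e-5, K_cap = 1e6) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(K) || length(K) != 1L || is.na(K) || K < 1 || K != round(K))
      stop("fixed mode requires a positive integer K", call. = FALSE)
    K <- as.integer(K)
  }
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon <= 0 || epsilon > 0.1)
    stop("epsilon must lie in (0, 0.1]", call. = FALSE)
  structure(list(mode = mode, K = K, epsilon = epsilon, K_cap = K_cap),
            class = "truncation_policy")
}

# upper-tail probability P(N > K) of the mixing distribution
mixing_tail <- function(K, params) {
  switch(params$family,
    poisson = stats::ppois(K, params$lambda, lower.tail = FALSE),
    negbin = stats::pnbinom(K, size = params$a, mu = params$lambda,
                            lower.tail = FALSE),
    zip = (1 - params$psi) *
      stats::ppois(K, params$lambda, lower.tail = FALSE))
}

# log mass of the mixing distribution at N = n (vectorized over n)
mixing_logpmf <- function(n, params) {
  switch(params$family,
    poisson = stats::dpois(n, params$lambda, log = TRUE),
    negbin = stats::dnbinom(n, size = params$a, mu = params$lambda,
                            log = TRUE),
    zip = {
      lp <- log1p(-params$psi) + stats::dpois(n, params$lambda, log = TRUE)
      if (params$psi > 0 && any(n == 0))
        lp[n == 0] <- logsumexp(c(log(params$psi), lp[n == 0]))
      lp
    })
}

#' Automatic choice of the truncation bound K
#'
#' Returns the smallest K with P(N > K) < epsilon under the mixing
#' distribution implied by `params`, floored at the largest observed count.
#' The tail rule uses the family's own cdf (Poisson, negative-binomial, or
#' zero-inflated Poisson).
#'
#' @param params an [nmix_params()] object (the *current* estimate during
#'   optimization).
#' @param policy a [truncation_policy()].
#' @param counts the observed [count_matrix()] (or a vector of counts);
#'   only its maximum is used, as the sum must start at max(y).
#' @return an integer K.
#' @export
choose_K <- function(params, policy = truncation_policy(), counts = 0L) {
  floor_K <- max(0L, max(counts))
  if (policy$mode == "fixed") return(max(policy$K, floor_K))
  eps <- policy$epsilon
  # quantile start, then exact integer scan to the minimal K
  K <- switch(params$family,
    poisson = stats::qpois(eps, params$lambda, lower.tail = FALSE),
    negbin = stats::qnbinom(eps, size = params$a, mu = params$lambda,
                            lower.tail = FALSE),
    zip = stats::qpois(eps, params$lambda, lower.tail = FALSE))
  K <- max(K, floor_K)
  if (K > policy$K_cap)
    stop("auto-K exceeded K_cap = ", policy$K_cap, call. = FALSE)
  while (K > floor_K && mixing_tail(K - 1L, params) < eps) K <- K - 1L
  while (mixing_tail(K, params) >= eps) {
    K <- K + 1L
    if (K > policy$K_cap)
      stop("auto-K exceeded K_cap = ", policy$K_cap, call. = FALSE)
  }
  as.integer(K)
}

#' Classical truncated N-mixture likelihood
#'
#' `site_likelihood_truncated()` evaluates the per-site probability
#' sum_\{N = max(y)\}^K f(N) prod_t Binomial(y_t; N, p) for mixing pmf f;
#' `loglik_truncated()` sums the log over sites (distinct rows evaluated
#' once). For K large enough this equals the exact multivariate pmf.
#'
#' @param y integer count vector for one site.
#' @param params an [nmix_params()] object.
#' @param K truncation bound, at least max(y).
#' @param log return the log probability?
#' @export
site_likelihood_truncated <- function(y, params, K, log = FALSE) {
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (K < max(y)) stop("K is below the largest observed count", call. = FALSE)
  N <- seq.int(max(y), K)
  lt <- mixing_logpmf(N, params)
  for (t in seq_along(y))
    lt <- lt + stats::dbinom(y[t], N, params$p, log = TRUE)
  lp <- logsumexp(lt)
  if (log) lp else exp(lp)
}

#' @rdname site_likelihood_truncated
#' @param counts a [count_matrix()] (or coercible).
#' @param policy a [truncation_policy()]; in auto mode K is derived from
#'   `params` on this call.
#' @return `loglik_truncated()`: the dataset log-likelihood, with the K
#'   actually used in attribute `"K"`.
#' @export
loglik_truncated <- function(counts, params, policy = truncation_policy()) {
  counts <- count_matrix(counts)
  K <- choose_K(params, policy, counts)
  key <- apply(counts, 1L, paste, collapse = ",")
  idx <- !duplicated(key)
  urows <- counts[idx, , drop = FALSE]
  mult <- as.vector(table(key)[key[idx]])
  lps <- vapply(seq_len(nrow(urows)), function(i)
    site_likelihood_truncated(urows[i, ], params, K, log = TRUE), numeric(1))
  if (any(!is.finite(lps)))
    stop("site probability underflowed to zero on the log scale",
         call. = FALSE)
  structure(sum(mult * lps), K = K)
}
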