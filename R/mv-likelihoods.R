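#' Exact multivariate N-mixture probability mass functions
#'
#' The Poisson N-mixture model for T repeat visits is exactly a multivariate
#' Poisson distribution: decomposing the individuals at a site by the subset
#' of occasions on which they were detected gives independent Poisson latent
#' counts n_s with rates theta_s = lambda * w_s, where w_s are the
#' [thinning_weights()]. The observed pmf is the sum over all latent
#' configurations consistent with y (the set A_y) of the product of Poisson
#' masses. With gamma mixing of the Poisson mean (shape a, rate b = a /
#' lambda) the sum integrates to the multivariate negative-binomial pmf
#'
#'   sum over A_y of \[prod_s w_s^(n_s) / n_s!\] Gamma(a + M) / Gamma(a)
#'     b^a / (b + W)^(a + M),
#'
#' with M the total of the configuration and W = 1 - (1-p)^T. The
#' zero-inflated Poisson mixes a point mass at N = 0: psi * 1\{y = 0\} +
#' (1 - psi) * multivariate Poisson. These forms need no truncation bound K;
#' they are evaluated in log space with log-sum-exp over configurations.
#'
#' @param y integer vector of counts at one site (length T).
#' @param lambda mean site abundance.
#' @param p detection probability in (0, 1).
#' @param a gamma shape of the negative-binomial mixing distribution.
#' @param psi zero-inflation probability.
#' @param log return the log pmf?
#' @return a single probability (or log probability).
#' @seealso [loglik_mv()] for whole-dataset log-likelihoods,
#'   [loglik_truncated()] for the classical truncated-sum formulation.
#' @examples
#' dmvpois(c(0, 0), lambda = 1, p = 0.5)  # exp(-0.75)
#' dbivpois(1, 1, lambda = 1, p = 0.5)
#' @export
dmvpois <- function(y, lambda, p, log = FALSE) {
  pars <- nmix_params("poisson", lambda = lambda, p = p)
  sys <- subset_system(length(y))
  pre <- precompute_site(sys, y)
  lp <- site_logpmf(pre, sys, pars)
  if (log) lp else exp(lp)
}

#' @rdname dmvpois
#' @export
dmvnbinom <- function(y, lambda, a, p, log = FALSE) {
  pars <- nmix_params("negbin", lambda = lambda, p = p, a = a)
  sys <- subset_system(length(y))
  pre <- precompute_site(sys, y)
  lp <- site_logpmf(pre, sys, pars)
  if (log) lp else exp(lp)
}

#' @rdname dmvpois
#' @export
dmvzip <- function(y, lambda, p, psi, log = FALSE) {
  pars <- nmix_params("zip", lambda = lambda, p = p, psi = psi)
  sys <- subset_system(length(y))
  pre <- precompute_site(sys, y)
  lp <- site_logpmf(pre, sys, pars)
  if (log) lp else exp(lp)
}

#' @rdname dmvpois
#' @param y1,y2 counts on the two visits (bivariate closed form, T = 2).
#' @export
dbivpois <- function(y1, y2, lambda, p, log = FALSE) {
  pars <- nmix_params("poisson", lambda = lambda, p = p)
  if (any(c(y1, y2) < 0) || any(c(y1, y2) != round(c(y1, y2))))
    stop("counts must be non-negative integers", call. = FALSE)
  th1 <- lambda * p * (1 - p)
  th12 <- lambda * p^2
  j <- 0:min(y1, y2)
  terms <- (y1 - j) * log(th1) + (y2 - j) * log(th1) + j * log(th12) -
    lfactorial(y1 - j) - lfactorial(y2 - j) - lfactorial(j)
  lp <- logsumexp(terms) - lambda * (1 - (1 - p)^2)
  if (log) lp else exp(lp)
}

#' Dataset log-likelihood under the multivariate formulation
#'
#' Sites are independent, so the dataset log-likelihood is the sum of the
#' per-site log pmfs. Identical site count vectors share one pmf
#' evaluation, so cost scales with the number of *distinct* rows, not S.
#'
#' @param counts a [count_matrix()] (or coercible).
#' @param params an [nmix_params()] object.
#' @return the log-likelihood (a finite scalar; underflow to exactly zero
#'   probability raises an error rather than returning -Inf silently).
#' @export
loglik_mv <- function(counts, params) {
  eng <- mv_engine(counts)
  engine_loglik(eng, params)
}

## ---- internal engine ----

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-site precomputation: configuration matrix and its fixed functionals
precompute_site <- function(sys, y) {
  C <- enumerate_configs(sys, y)
  list(C = C,
       lfact = rowSums(lfactorial(C)),
       M = rowSums(C),
       zero = all(y == 0L))
}

# log pmf of one site given precomputed configurations
site_logpmf <- function(pre, sys, params) {
  p <- params$p; lambda <- params$lambda
  logw <- sys$sizes * log(p) + (sys$T - sys$sizes) * log1p(-p)
  logw[!is.finite(logw)] <- -1e8  # p at machine edge: keep 0 * logw finite
  W <- 1 - (1 - p)^sys$T
  fam <- params$family
  if (fam == "poisson" || fam == "zip") {
    terms <- drop(pre$C %*% logw) + pre$M * log(lambda) - pre$lfact
    lp <- logsumexp(terms) - lambda * W
    if (fam == "zip") {
      psi <- params$psi
      if (psi > 0) {
        lp <- if (pre$zero) logsumexp(c(log(psi), log1p(-psi) + lp))
              else log1p(-psi) + lp
      }
    }
    lp
  } else {  # negbin: gamma shape a, rate b = a / lambda
    a <- params$a; b <- a / lambda
    terms <- drop(pre$C %*% logw) - pre$lfact +
      lgamma(a + pre$M) - lgamma(a) +
      a * log(b) - (a + pre$M) * log(b + W)
    logsumexp(terms)
  }
}

# dataset engine: distinct rows, their multiplicities, and per-row configs
mv_engine <- function(counts) {
  counts <- count_matrix(counts)
  sys <- subset_system(ncol(counts))
  key <- apply(counts, 1L, paste, collapse = ",")
  idx <- !duplicated(key)
  urows <- counts[idx, , drop = FALSE]
  mult <- as.vector(table(key)[key[idx]])
  pre <- lapply(seq_len(nrow(urows)), function(i)
    precompute_site(sys, urows[i, ]))
  structure(list(sys = sys, urows = urows, mult = mult, pre = pre,
                 S = nrow(counts)),
            class = "mv_engine")
}

engine_loglik <- function(eng, params) {
  lps <- vapply(eng$pre, site_logpmf, numeric(1),
                sys = eng$sys, params = params)
  if (any(!is.finite(lps)))
    stop("site probability underflowed to zero on the log scale",
         call. = FALSE)
  sum(eng$mult * lps)
}
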