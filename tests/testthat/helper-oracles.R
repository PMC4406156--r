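# Brute-force oracles: direct evaluation of the N-mixture mixture sum
# sum_N f(N) prod_t Binomial(y_t; N, p), independent of the package's
# subset-decomposition machinery.

oracle_mixture_pmf <- function(y, p, mixing_logpmf, K = 1000L) {
  N <- seq.int(max(y), K)
  lt <- mixing_logpmf(N)
  for (t in seq_along(y)) lt <- lt + dbinom(y[t], N, p, log = TRUE)
  sum(exp(lt))
}

oracle_pois_pmf <- function(y, lambda, p, K = 1000L)
  oracle_mixture_pmf(y, p, function(N) dpois(N, lambda, log = TRUE), K)

oracle_nb_pmf <- function(y, lambda, a, p, K = 1000L)
  oracle_mixture_pmf(y, p, function(N) dnbinom(N, size = a, mu = lambda,
                                               log = TRUE), K)

# exhaustive grid-scan enumeration oracle: every latent vector with
# entries in 0..max(y) over all non-empty subsets, kept iff the
# per-occasion sum constraints hold
oracle_enumerate <- function(T, y) {
  subsets <- unlist(lapply(seq_len(T), function(k)
    utils::combn(T, k, simplify = FALSE)), recursive = FALSE)
  # canonical order: size ascending then lexicographic (combn is lex)
  subsets <- subsets[order(lengths(subsets))]
  grid <- do.call(expand.grid, rep(list(0:max(y, 0)), length(subsets)))
  keep <- apply(grid, 1L, function(n) {
    all(vapply(seq_len(T), function(t)
      sum(n[vapply(subsets, function(s) t %in% s, logical(1))]) == y[t],
      logical(1)))
  })
  unname(as.matrix(grid[keep, , drop = FALSE]))
}

# moment-level simulation helper shared by several tests
sim_counts_raw <- function(S, T, lambda, p, family = "poisson", a = NULL) {
  N <- if (family == "poisson") rpois(S, lambda)
       else rnbinom(S, size = a, mu = lambda)
  matrix(rbinom(S * T, size = rep(N, times = T), prob = p), nrow = S)
}
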