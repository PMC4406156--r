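#' Simulate replicated count surveys
#'
#' Draws site abundances N_i from the mixing distribution (Poisson,
#' NB-2 negative-binomial with gamma shape `a`, or zero-inflated Poisson
#' with unoccupied probability `psi`) and then T independent binomial
#' thinnings y_it | N_i ~ Binomial(N_i, p).
#'
#' @param S number of sites.
#' @param T number of visits.
#' @param lambda mean site abundance.
#' @param p detection probability.
#' @param family mixing family.
#' @param a gamma shape (negbin).
#' @param psi zero-inflation probability (zip).
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a [count_matrix()].
#' @export
simulate_counts <- function(S, T, lambda, p,
                            family = c("poisson", "negbin", "zip"),
                            a = NULL, psi = NULL, seed = NULL) {
  family <- match.arg(family)
  pars <- nmix_params(family, lambda = lambda, p = min(p, 1 - 1e-12),
                      a = a, psi = psi)
  draw <- function() {
    N <- switch(family,
      poisson = stats::rpois(S, lambda),
      negbin = stats::rnbinom(S, size = a, mu = lambda),
      zip = stats::rpois(S, lambda) *
        (stats::runif(S) >= psi))
    count_matrix(matrix(stats::rbinom(S * T, size = rep(N, times = T),
                                      prob = p), nrow = S))
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# deterministic child seed for scenario i, replicate r under a root seed;
# kept below 2^31 - 1
child_seed <- function(seed, scenario, rep) {
  as.integer((as.double(seed) * 48271 + scenario * 1664525 + rep * 1013904223) %%
               2147483647)
}

#' Scenario grids for the simulation studies
#'
#' `table1_scenarios()` is the Poisson study grid: S = 20 sites,
#' lambda in \{2, 5, 10\}, p in \{0.10, 0.25\}, T in \{2, 3, 4\}.
#' `table2_scenarios()` is the negative-binomial study grid: S = 20,
#' lambda in \{2, 5, 10\}, p in \{0.10, 0.25\}, gamma shape
#' a in \{1.25, 5\}, T in \{2, 3\}.
#'
#' @return a data frame with one row per scenario.
#' @export
table1_scenarios <- function() {
  g <- expand.grid(T = c(2L, 3L, 4L), p = c(0.10, 0.25), lambda = c(2, 5, 10),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(lambda = g$lambda, p = g$p, T = g$T, S = 20L)
}

#' @rdname table1_scenarios
#' @export
table2_scenarios <- function() {
  g <- expand.grid(T = c(2L, 3L), a = c(1.25, 5), p = c(0.10, 0.25),
                   lambda = c(2, 5, 10), KEEP.OUT.ATTRS = FALSE)
  data.frame(lambda = g$lambda, p = g$p, a = g$a, T = g$T, S = 20L)
}

#' Poisson diagnostic study (EPN / EPD)
#'
#' For each scenario simulates `n_sim` datasets and reports EPN, the
#' proportion whose covariance diagnostic D1 is negative, and (optionally)
#' EPD, the proportion whose Poisson MLE of lambda is classified as
#' infinite by the boundary rule of [fit_nmix()]. The two proportions
#' correspond closely.
#'
#' @param scenarios data frame with columns `lambda`, `p`, `T`, `S`
#'   (default [table1_scenarios()]).
#' @param n_sim replicates per scenario.
#' @param seed root seed; per-replicate child seeds are derived
#'   deterministically, so scenarios can run in any order.
#' @param compute_epd fit the MLE for EPD? (much slower than EPN).
#' @param negative `"nonpositive"` counts D <= 0, `"strict"` counts D < 0.
#' @param ... further arguments passed to [fit_nmix()].
#' @return data frame: one row per scenario with `EPN`, `EPN_se`, and when
#'   requested `EPD`, `EPD_se`, `n_fit_error`.
#' @export
run_epn_epd <- function(scenarios = table1_scenarios(), n_sim = 1000L,
                        seed = 1L, compute_epd = FALSE,
                        negative = c("nonpositive", "strict"), ...) {
  negative <- match.arg(negative)
  is_neg <- if (negative == "strict") function(d) d < 0 else function(d) d <= 0
  out <- scenarios
  out$EPN <- out$EPN_se <- NA_real_
  if (compute_epd) { out$EPD <- out$EPD_se <- NA_real_; out$n_fit_error <- 0L }
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    neg <- 0L; inf <- 0L; err <- 0L
    for (r in seq_len(n_sim)) {
      y <- simulate_counts(sc$S, sc$T, sc$lambda, sc$p, "poisson",
                           seed = child_seed(seed, i, r))
      if (is_neg(cov_diagnostic(y))) neg <- neg + 1L
      if (compute_epd) {
        f <- try(fit_nmix(y, "poisson", seed = child_seed(seed, i, r) %% 1e6,
                          ...), silent = TRUE)
        if (inherits(f, "try-error")) err <- err + 1L
        else if (f$boundary_infinite) inf <- inf + 1L
      }
    }
    out$EPN[i] <- neg / n_sim
    out$EPN_se[i] <- sqrt(out$EPN[i] * (1 - out$EPN[i]) / n_sim)
    if (compute_epd) {
      n_ok <- n_sim - err
      out$EPD[i] <- inf / n_ok
      out$EPD_se[i] <- sqrt(out$EPD[i] * (1 - out$EPD[i]) / n_ok)
      out$n_fit_error[i] <- err
    }
  }
  out
}

#' Negative-binomial diagnostic study
#'
#' For each scenario simulates `n_sim` negative-binomial datasets and
#' reports the joint sign proportions of the two diagnostics (D1, D2) and,
#' for the requested sign groups, the conditional proportion of
#' negative-binomial MLE fits classified as infinite. The published study
#' counts strictly negative diagnostics, which matters for sparse data
#' where D2 has a point mass at exactly zero; hence `negative = "strict"`
#' by default here.
#'
#' @param scenarios data frame with columns `lambda`, `p`, `a`, `T`, `S`
#'   (default [table2_scenarios()]).
#' @param n_sim replicates per scenario.
#' @param seed root seed (deterministic child seeds per replicate).
#' @param fit_groups which diagnostic sign groups to fit by maximum
#'   likelihood: subset of `c("both_negative", "both_positive")`.
#' @param max_fits_per_group cap on fits per scenario and group; when a
#'   group is larger, a seeded random subsample of that size is fitted
#'   (the conditional proportion stays unbiased).
#' @param negative sign convention for "negative", as in [run_epn_epd()].
#' @param ... further arguments passed to [fit_nmix()].
#' @return data frame with per-scenario columns `p_both_neg`, `p_any_neg`,
#'   `p_both_pos`, and per requested group `n_<group>`, `n_fit_<group>`,
#'   `p_inf_<group>` (NA when the group is empty), `n_err_<group>`.
#' @export
run_nb_diag_study <- function(scenarios = table2_scenarios(), n_sim = 1000L,
                              seed = 1L, fit_groups = "both_negative",
                              max_fits_per_group = Inf,
                              negative = c("strict", "nonpositive"), ...) {
  negative <- match.arg(negative)
  is_neg <- if (negative == "strict") function(d) d < 0 else function(d) d <= 0
  if (length(fit_groups) > 0L)
    fit_groups <- match.arg(fit_groups, c("both_negative", "both_positive"),
                            several.ok = TRUE)
  out <- scenarios
  out$p_both_neg <- out$p_any_neg <- out$p_both_pos <- NA_real_
  for (g in fit_groups) {
    out[[paste0("n_", g)]] <- NA_integer_
    out[[paste0("n_fit_", g)]] <- 0L
    out[[paste0("p_inf_", g)]] <- NA_real_
    out[[paste0("n_err_", g)]] <- 0L
  }
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    seeds <- vapply(seq_len(n_sim), function(r) child_seed(seed, i, r),
                    integer(1))
    sims <- lapply(seeds, function(s)
      simulate_counts(sc$S, sc$T, sc$lambda, sc$p, "negbin", a = sc$a,
                      seed = s))
    d1 <- vapply(sims, cov_diagnostic, numeric(1))
    d2 <- vapply(sims, nb_diagnostic, numeric(1))
    grp <- list(both_negative = which(is_neg(d1) & is_neg(d2)),
                both_positive = which(!is_neg(d1) & !is_neg(d2)))
    out$p_both_neg[i] <- length(grp$both_negative) / n_sim
    out$p_both_pos[i] <- length(grp$both_positive) / n_sim
    out$p_any_neg[i] <- sum(is_neg(d1) | is_neg(d2)) / n_sim
    for (g in fit_groups) {
      members <- grp[[g]]
      out[[paste0("n_", g)]][i] <- length(members)
      if (length(members) == 0L) next
      sel <- members
      if (length(sel) > max_fits_per_group)
        sel <- with_preserved_seed(child_seed(seed, i, n_sim + 1L),
                                   sample(members, max_fits_per_group))
      inf <- 0L; err <- 0L
      for (j in sel) {
        f <- try(fit_nmix(sims[[j]], "negbin", seed = seeds[j] %% 1e6, ...),
                 silent = TRUE)
        if (inherits(f, "try-error")) err <- err + 1L
        else if (f$boundary_infinite) inf <- inf + 1L
      }
      n_ok <- length(sel) - err
      out[[paste0("n_fit_", g)]][i] <- length(sel)
      out[[paste0("p_inf_", g)]][i] <- if (n_ok > 0) inf / n_ok else NA_real_
      out[[paste0("n_err_", g)]][i] <- err
    }
  }
  out
}

#' Mean conditional infinite proportion over scenarios
#'
#' Averages a per-scenario conditional proportion over the scenarios where
#' the conditioning group was non-empty (scenarios with empty groups are
#' dropped, as the published summaries do).
#'
#' @param study result of [run_nb_diag_study()].
#' @param group `"both_negative"` or `"both_positive"`.
#' @export
mean_conditional_infinite <- function(study, group = "both_negative") {
  v <- study[[paste0("p_inf_", group)]]
  mean(v[!is.na(v)])
}

#' Effect of a fixed truncation bound K on the abundance MLE
#'
#' Simulates Poisson N-mixture datasets once, then fits the truncated
#' likelihood with each fixed K in `K_list`. On datasets whose covariance
#' diagnostic is negative the abundance estimate piles up near the ceiling
#' imposed by K, so the upper mode of the sampling distribution of
#' lambda-hat grows with K.
#'
#' @param lambda,p,S,T scenario parameters.
#' @param K_list fixed truncation bounds to compare.
#' @param n_sim simulated datasets.
#' @param seed root seed.
#' @param ... passed to [fit_nmix()].
#' @return data frame with columns `K`, `rep`, `lambda_hat`, `boundary`,
#'   `D1` (one row per dataset and K).
#' @export
run_k_sensitivity <- function(lambda = 2, p = 0.1, S = 20L, T = 2L,
                              K_list = c(100L, 200L, 400L), n_sim = 100L,
                              seed = 1L, ...) {
  sims <- lapply(seq_len(n_sim), function(r)
    simulate_counts(S, T, lambda, p, "poisson",
                    seed = child_seed(seed, 1L, r)))
  d1 <- vapply(sims, cov_diagnostic, numeric(1))
  res <- list()
  for (K in K_list) {
    pol <- truncation_policy("fixed", K = K)
    lam_hat <- rep(NA_real_, n_sim); bnd <- rep(NA, n_sim)
    for (r in seq_len(n_sim)) {
      f <- try(fit_nmix(sims[[r]], "poisson", formulation = "truncated",
                        policy = pol, infinite_threshold = Inf,
                        max_rounds = 3L,
                        seed = child_seed(seed, 2L, r) %% 1e6, ...),
               silent = TRUE)
      if (!inherits(f, "try-error")) {
        lam_hat[r] <- f$estimates$lambda
        bnd[r] <- f$estimates$lambda > 0.5 * K
      }
    }
    res[[length(res) + 1L]] <- data.frame(K = K, rep = seq_len(n_sim),
                                          lambda_hat = lam_hat,
                                          boundary = bnd, D1 = d1)
  }
  do.call(rbind, res)
}

#' Design subsampling of an observed survey
#'
#' Repeatedly draws a random subset of sites (and, optionally, of visits)
#' without replacement from an observed count matrix and recomputes the
#' covariance diagnostic, estimating how often a smaller design would have
#' produced a non-positive diagnostic -- the workflow used to show that
#' fewer sites or visits inflate the risk of infinite abundance estimates.
#'
#' @param counts a [count_matrix()] (or coercible).
#' @param S_keep sites per subsample.
#' @param T_keep visits per subsample (>= 2).
#' @param n_draws number of subsamples.
#' @param seed seed for reproducibility.
#' @return proportion of subsamples with D1 <= 0, with attribute
#'   `"draws"` holding the per-draw diagnostics.
#' @export
subsample_design <- function(counts, S_keep, T_keep = NULL, n_draws = 1000L,
                             seed = 1L) {
  counts <- count_matrix(counts)
  if (is.null(T_keep)) T_keep <- ncol(counts)
  if (S_keep > nrow(counts) || S_keep < 2L)
    stop("S_keep must lie in 2..S", call. = FALSE)
  if (T_keep > ncol(counts) || T_keep < 2L)
    stop("T_keep must lie in 2..T", call. = FALSE)
  d1 <- with_preserved_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      rows <- sample(nrow(counts), S_keep)
      cols <- if (T_keep == ncol(counts)) seq_len(ncol(counts))
              else sort(sample(ncol(counts), T_keep))
      cov_diagnostic(counts[rows, cols, drop = FALSE])
    }, numeric(1))
  })
  structure(mean(d1 <= 0), draws = d1)
}
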