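#' Non-empty subsets of sampling occasions
#'
#' The multivariate reformulation of the N-mixture model decomposes the count
#' at occasion t into contributions from the latent variables n_s, one for
#' each non-empty subset s of occasions: n_s counts the individuals detected
#' on exactly the occasions in s. `subset_system()` enumerates the 2^T - 1
#' subsets in a canonical order: by subset size ascending, then
#' lexicographically by occasion labels. The canonical order gives every
#' module the same stable indexing of the subset rates.
#'
#' @param T number of sampling occasions (1 <= T <= 10; the latent dimension
#'   is 2^T - 1, so larger T is refused rather than attempted).
#' @return an object of class `"subset_system"`: a list with `T`, `subsets`
#'   (list of integer vectors of occasion labels), `sizes`, and `membership`
#'   (for each occasion, the indices of the subsets containing it).
#' @examples
#' ss <- subset_system(2)
#' ss$subsets  # {1}, {2}, {1,2}
#' @export
subset_system <- function(T) {
  if (length(T) != 1L || is.na(T) || T != round(T) || T < 1)
    stop("T must be a positive integer", call. = FALSE)
  if (T > 10) stop("T > 10: latent dimension 2^T - 1 is too large", call. = FALSE)
  T <- as.integer(T)
  subsets <- list()
  for (size in seq_len(T)) {
    combos <- utils::combn(T, size, simplify = FALSE)
    subsets <- c(subsets, combos)  # combn is already lexicographic
  }
  membership <- lapply(seq_len(T), function(t)
    which(vapply(subsets, function(s) t %in% s, logical(1))))
  structure(list(T = T, subsets = subsets,
                 sizes = lengths(subsets), membership = membership),
            class = "subset_system")
}

#' @export
print.subset_system <- function(x, ...) {
  cat(sprintf("subset system: T = %d, %d non-empty subsets\n",
              x$T, length(x$subsets)))
  invisible(x)
}

#' Binomial thinning weights over occasion subsets
#'
#' An individual present at a site is detected on the occasions in subset s
#' with probability w_s = p^|s| (1-p)^(T-|s|). Under Poisson abundance with
#' mean lambda, the latent subset counts are independent Poisson with rates
#' theta_s = lambda * w_s. The weights sum to 1 - (1-p)^T, the probability
#' of being detected at least once.
#'
#' @param sys a [subset_system()].
#' @param p per-individual, per-visit detection probability in (0, 1).
#' @return numeric vector of weights, one per subset in canonical order.
#' @export
thinning_weights <- function(sys, p) {
  stopifnot(inherits(sys, "subset_system"))
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("p must lie in (0, 1)", call. = FALSE)
  p^sys$sizes * (1 - p)^(sys$T - sys$sizes)
}

#' Enumerate latent configurations consistent with an observed count vector
#'
#' Lists every non-negative integer assignment of the latent subset counts
#' n_s such that, for each occasion t, the n_s over subsets containing t sum
#' to the observed count y_t. The enumeration is a depth-first search over
#' subsets in canonical order, maintaining per-occasion remaining budgets;
#' each n_s ranges over 0..min of the budgets of the occasions in s, and a
#' branch is pruned as soon as some occasion with remaining budget can no
#' longer be covered. For T = 2 the number of configurations is
#' min(y1, y2) + 1.
#'
#' The configuration count grows combinatorially with T and with the
#' counts, so the exact multivariate formulation is practical for few
#' visits (T = 2 or 3, the designs where infinite estimates are a real
#' risk) or small counts; `max_configs` guards against runaway
#' enumeration, and the truncated formulation covers the rest.
#'
#' @param sys a [subset_system()].
#' @param y integer vector of length `sys$T`, the counts at one site.
#' @param max_configs enumeration guard; exceeding it is an error.
#' @return an integer matrix with one row per configuration and one column
#'   per subset (canonical order); attribute `y` stores the count vector.
#' @export
enumerate_configs <- function(sys, y, max_configs = 2e5) {
  stopifnot(inherits(sys, "subset_system"))
  if (length(y) != sys$T) stop("y must have length T", call. = FALSE)
  if (any(is.na(y)) || any(y < 0) || any(y != round(y)))
    stop("y must be non-negative integers", call. = FALSE)
  y <- as.integer(y)
  nsub <- length(sys$subsets)
  # last subset index covering each occasion, for the coverage prune
  last_cover <- vapply(seq_len(sys$T), function(t) max(sys$membership[[t]]),
                       integer(1))
  out <- vector("list", 64L); n_out <- 0L
  cfg <- integer(nsub)
  rec <- function(j, budget) {
    if (j > nsub) {
      if (all(budget == 0L)) {
        n_out <<- n_out + 1L
        if (n_out > max_configs)
          stop("latent configuration set exceeds ", max_configs,
               " elements; use the truncated formulation", call. = FALSE)
        out[[n_out]] <<- cfg
      }
      return(invisible())
    }
    # occasions that can never be covered again must have zero budget
    dead <- which(last_cover < j)
    if (any(budget[dead] > 0L)) return(invisible())
    s <- sys$subsets[[j]]
    hi <- min(budget[s])
    forced <- s[last_cover[s] == j]
    if (length(forced) > 0L) {
      # n_j must finish these occasions exactly
      v <- unique(budget[forced])
      if (length(v) > 1L || v > hi) return(invisible())
      lo <- v; hi <- v
    } else lo <- 0L
    for (n in lo:hi) {
      cfg[j] <<- n
      b <- budget; b[s] <- b[s] - n
      rec(j + 1L, b)
    }
    cfg[j] <<- 0L
    invisible()
  }
  rec(1L, y)
  m <- if (n_out == 0L) matrix(integer(0), 0L, nsub)
       else do.call(rbind, out[seq_len(n_out)])
  attr(m, "y") <- y
  m
}
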