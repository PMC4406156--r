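#' Model parameters for the N-mixture families
#'
#' All three mixing families share the mean site abundance `lambda` and the
#' per-individual, per-visit detection probability `p`. The
#' negative-binomial family adds the gamma shape `a`: the latent Poisson
#' mean is gamma distributed with mean `lambda` and rate `b = a / lambda`,
#' the NB-2 parameterization, so the coefficient of variation of the Poisson
#' mean is `1/sqrt(a)` and `lambda` is the mean abundance in every family.
#' The zero-inflated Poisson family adds the zero-inflation mass `psi`: a
#' site is unoccupied (N = 0) with probability `psi`, otherwise N is
#' Poisson(`lambda`).
#'
#' @param family one of `"poisson"`, `"negbin"`, `"zip"`.
#' @param lambda mean site abundance, > 0.
#' @param p detection probability, in (0, 1).
#' @param a gamma shape (negbin only), > 0.
#' @param psi zero-inflation probability (zip only), in \[0, 1).
#' @return a list of class `"nmix_params"`.
#' @export
nmix_params <- function(family = c("poisson", "negbin", "zip"),
                        lambda, p, a = NULL, psi = NULL) {
  family <- match.arg(family)
  chk <- function(val, name, lo, hi, lo_ok = FALSE) {
    if (length(val) != 1L || is.na(val))
      stop(name, " must be a single finite number", call. = FALSE)
    if (val < lo || (!lo_ok && val == lo) || val >= hi)
      stop(sprintf("%s out of range", name), call. = FALSE)
  }
  chk(lambda, "lambda", 0, Inf)
  chk(p, "p", 0, 1)
  if (family == "negbin") {
    if (is.null(a)) stop("negbin family requires gamma shape a", call. = FALSE)
    chk(a, "a", 0, Inf)
  } else a <- NULL
  if (family == "zip") {
    if (is.null(psi)) stop("zip family requires psi", call. = FALSE)
    chk(psi, "psi", 0, 1, lo_ok = TRUE)
  } else psi <- NULL
  structure(list(family = family, lambda = lambda, p = p, a = a, psi = psi),
            class = "nmix_params")
}

#' @export
print.nmix_params <- function(x, ...) {
  extra <- switch(x$family,
    negbin = sprintf(", a = %g", x$a),
    zip = sprintf(", psi = %g", x$psi),
    "")
  cat(sprintf("%s N-mixture parameters: lambda = %g, p = %g%s\n",
              x$family, x$lambda, x$p, extra))
  invisible(x)
}
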