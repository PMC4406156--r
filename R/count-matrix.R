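#' Validated site-by-occasion count matrix
#'
#' An N-mixture survey dataset is an S x T matrix of non-negative integer
#' counts: one row per site, one column per repeat visit (occasion). The
#' design is balanced; missing visits are rejected rather than imputed,
#' because the exact likelihoods and the moment diagnostics all assume a
#' rectangular design.
#'
#' @param x a numeric matrix, data frame, or vector coercible to a matrix of
#'   non-negative integers. A vector is taken as a single site.
#' @return an integer matrix of class `"count_matrix"` with attributes `S`
#'   (sites) and `T` (occasions).
#' @examples
#' y <- count_matrix(rbind(c(1, 2), c(0, 3)))
#' n_sites(y)
#' n_occasions(y)
#' @export
count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.numeric(x)) stop("counts must be numeric", call. = FALSE)
  if (length(x) == 0L) stop("empty count matrix", call. = FALSE)
  if (anyNA(x)) stop("missing values in counts: the design must be balanced",
                     call. = FALSE)
  if (any(x < 0)) stop("negative count", call. = FALSE)
  if (any(x != round(x))) stop("non-integer count", call. = FALSE)
  m <- matrix(as.integer(round(x)), nrow = nrow(x), ncol = ncol(x))
  structure(m, class = c("count_matrix", "matrix"),
            S = nrow(m), T = ncol(m))
}

#' @rdname count_matrix
#' @export
n_sites <- function(x) nrow(x)

#' @rdname count_matrix
#' @export
n_occasions <- function(x) ncol(x)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix: %d sites x %d occasions, %d detections\n",
              nrow(x), ncol(x), sum(x)))
  m <- x
  attributes(m) <- attributes(m)[c("dim")]
  dimnames(m) <- list(site = seq_len(nrow(m)),
                      occasion = seq_len(ncol(m)))
  print(utils::head(m, 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more sites\n", nrow(x) - 10L))
  invisible(x)
}

#' Read and write survey counts as CSV
#'
#' Plain CSV with one row per site and one column per occasion. A header row
#' is auto-detected on read: if the first row contains any non-numeric cell
#' it is treated as column labels.
#'
#' @param path file path.
#' @return `read_count_csv()` returns a [count_matrix()].
#' @export
read_count_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1L,
                           colClasses = "character",
                           strip.white = TRUE)
  header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = header, strip.white = TRUE)
  count_matrix(df)
}

#' @rdname read_count_csv
#' @param x a count matrix.
#' @export
write_count_csv <- function(x, path) {
  x <- count_matrix(x)
  m <- unclass(x)
  attr(m, "S") <- NULL; attr(m, "T") <- NULL
  colnames(m) <- paste0("occ", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
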