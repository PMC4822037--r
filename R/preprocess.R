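# Microarray-style preprocessing: quantile normalization and log2 transform.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the rank-wise mean of the per-column sorted values, preserving ranks
#' within each column. Tied values within a column receive the mean of the
#' reference values at their tied rank positions. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' The operation is idempotent: once all columns share the reference
#' distribution, re-applying it is a no-op (up to arithmetic tolerance).
#'
#' @param matrix numeric matrix, features x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  validate_matrix(matrix, allow_missing = FALSE)
  if (nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("quantile normalization needs at least one feature and one sample",
         call. = FALSE)
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Log2-transform an expression matrix
#'
#' @param matrix numeric matrix, features x samples.
#' @param pseudocount non-negative offset added before taking logs.
#' @return \code{log2(matrix + pseudocount)}, same shape and dimnames.
#' @export
log2_transform <- function(matrix, pseudocount = 0) {
  validate_matrix(matrix)
  check_scalar_number(pseudocount, "pseudocount", nonnegative = TRUE)
  shifted <- matrix + pseudocount
  bad <- which(!is.na(shifted) & shifted <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(matrix))
    stop(sprintf(
      "non-positive value %g at (%s, %s) cannot be log-transformed with pseudocount %g",
      matrix[bad[1L]], rownames(matrix)[i[1L]], colnames(matrix)[i[2L]],
      pseudocount), call. = FALSE)
  }
  log2(shifted)
}
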