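# Per-sample pro-angiogenic signature score.
#
# For a panel of N pro-angiogenic genes, each sample gets, per gene, +1 if
# its expression lies strictly above that gene's median across all samples
# and -1 otherwise (ties included in "otherwise"). The signature score is
# the mean of these indicators:
#
#   score_s = (1/N) * sum_n sign_{n,s},   sign in {-1, +1}
#
# so every score lies in [-1, +1] and score*N is an integer with the parity
# of N. Being rank-based, the score is invariant under any strictly
# increasing per-gene transform of the expression values. Medians are always
# recomputed on the full sample set passed in.

#' Filter a gene panel down to genes consistently expressed in a matrix
#'
#' A panel gene is retained when it is present in the matrix and exceeds
#' `expression_floor` in at least `min_fraction_expressed` of samples.
#' Dropped genes and the reason ("absent" or "low") are reported via
#' \code{message()} and attached as the `"dropped"` attribute.
#'
#' @param matrix numeric expression matrix, features x samples.
#' @param panel character vector of panel gene symbols.
#' @param min_fraction_expressed required fraction of samples above the floor.
#' @param expression_floor expression value a sample must exceed to count as
#'   expressed (platform low/missing sentinel).
#' @return the retained sub-panel, in panel order, with a `"dropped"`
#'   attribute (data.frame of gene/reason).
#' @export
select_consistent_genes <- function(matrix, panel,
                                    min_fraction_expressed = 0.8,
                                    expression_floor = 0) {
  validate_matrix(matrix)
  panel <- as_gene_panel(panel)
  check_scalar_number(min_fraction_expressed, "min_fraction_expressed",
                      nonnegative = TRUE)
  present <- panel %in% rownames(matrix)
  reason <- character(0)
  dropped <- character(0)
  keep <- character(0)
  for (g in panel) {
    if (!g %in% rownames(matrix)) {
      dropped <- c(dropped, g); reason <- c(reason, "absent")
      next
    }
    frac <- mean(matrix[g, ] > expression_floor, na.rm = TRUE)
    if (is.nan(frac) || frac < min_fraction_expressed) {
      dropped <- c(dropped, g); reason <- c(reason, "low")
    } else {
      keep <- c(keep, g)
    }
  }
  if (length(dropped))
    message("dropped ", length(dropped), " panel gene(s): ",
            paste0(dropped, " (", reason, ")", collapse = ", "))
  if (length(keep) == 0L)
    stop("no panel gene passed the consistency filter; score undefined",
         call. = FALSE)
  structure(keep, dropped = data.frame(gene = dropped, reason = reason,
                                       stringsAsFactors = FALSE))
}

#' Above-median sign matrix for a gene panel
#'
#' @param matrix numeric expression matrix, features x samples; panel rows
#'   must be complete (no missing values).
#' @param panel character vector of panel genes, all present in the matrix.
#' @return a panel x samples matrix of +1/-1: +1 where the sample's value is
#'   strictly above that gene's across-all-samples median, -1 otherwise
#'   (ties map to -1).
#' @export
median_sign_matrix <- function(matrix, panel) {
  validate_matrix(matrix)
  panel <- as_gene_panel(panel)
  missing <- setdiff(panel, rownames(matrix))
  if (length(missing))
    stop("panel gene(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- matrix[panel, , drop = FALSE]
  if (anyNA(sub))
    stop("missing values in panel rows; filter or impute first", call. = FALSE)
  med <- apply(sub, 1L, stats::median)
  signs <- ifelse(sub > med, 1, -1)
  dimnames(signs) <- dimnames(sub)
  signs
}

#' Pro-angiogenic signature score per sample
#'
#' The mean over panel genes of the +/-1 above-median indicators from
#' [median_sign_matrix()].
#'
#' @inheritParams median_sign_matrix
#' @return named numeric vector of per-sample scores in [-1, +1], one per
#'   matrix column, in column order.
#' @examples
#' m <- rbind(VEGFA = c(1, 5, 10), IL6 = c(4, 2, 8))
#' colnames(m) <- paste0("s", 1:3)
#' angiogenesis_score(m, c("VEGFA", "IL6"))  # -1 -1 +1
#' @export
angiogenesis_score <- function(matrix, panel) {
  signs <- median_sign_matrix(matrix, panel)
  colMeans(signs)
}
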