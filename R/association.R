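# Spearman-correlation layers: miRNA vs signature score, vs individual
# genes, and vs per-probe tracks (methylation beta values, copy number).

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks on
#' ties) on complete pairs, with a two-sided p-value from the t
#' approximation on n-2 degrees of freedom. For n <= 9 an exact
#' permutation p-value is available via `exact = TRUE`.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact logical; use the exact null distribution (only for n <= 9,
#'   tie-free data).
#' @return a one-row data.frame with `rho`, `p_value`, `n` (complete pairs)
#'   and `defined` (FALSE when either vector is constant, in which case rho
#'   is NA and the result is flagged rather than a silent NaN).
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(data.frame(rho = NA_real_, p_value = NA_real_, n = n,
                      defined = FALSE))
  if (exact && n > 9L)
    stop("exact permutation p-value supported only for n <= 9", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = "two.sided"))
  data.frame(rho = unname(ct$estimate), p_value = min(ct$p.value, 1),
             n = n, defined = TRUE)
}

# Shared machinery: correlate each row of `mat` against `target` over the
# shared samples, rank ascending by rho (most negative first, ties broken
# lexicographically by feature name).
correlate_rows <- function(mat, target, flag_p = NULL, min_pairs = 3L) {
  shared <- intersect(colnames(mat), names(target))
  if (length(shared) < min_pairs)
    stop("fewer than ", min_pairs, " shared samples", call. = FALSE)
  res <- lapply(rownames(mat), function(f) {
    xs <- mat[f, shared]
    ok <- is.finite(xs) & is.finite(target[shared])
    if (sum(ok) < min_pairs)
      return(data.frame(feature = f, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), defined = FALSE, skipped = TRUE))
    r <- spearman_cor(xs, target[shared])
    cbind(feature = f, r, skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  def <- out$defined & !out$skipped
  out$q_value[def] <- stats::p.adjust(out$p_value[def], method = "BH")
  if (!is.null(flag_p)) out$flagged <- def & out$p_value < flag_p
  out[order(out$rho, out$feature, na.last = TRUE), , drop = FALSE]
}

#' Correlate every miRNA with the angiogenesis score
#'
#' One Spearman correlation per miRNA over the samples shared between the
#' expression matrix and the score vector, ranked most-negative rho first.
#' Benjamini-Hochberg q-values are reported alongside the nominal p; the
#' shortlist criterion (nominal p below `flag_p`) is reported as a flag.
#'
#' @param mirna_expr miRNA expression matrix (miRNAs x samples).
#' @param scores named per-sample score vector, e.g. from
#'   [angiogenesis_score()].
#' @param flag_p nominal p-value threshold for the shortlist flag
#'   (default 1e-4).
#' @return data.frame with columns `feature`, `rho`, `p_value`, `n`,
#'   `defined`, `skipped`, `q_value`, `flagged`, sorted ascending by rho.
#' @export
correlate_with_score <- function(mirna_expr, scores, flag_p = 1e-4) {
  validate_matrix(mirna_expr)
  correlate_rows(mirna_expr, scores, flag_p = flag_p)
}

#' Correlate one miRNA with a list of genes
#'
#' @param mirna named per-sample expression vector for one miRNA.
#' @param mrna_expr mRNA expression matrix (genes x samples).
#' @param gene_list genes to test; genes absent from the matrix are ignored.
#'   An empty list yields an empty result.
#' @param flag_p nominal p-value threshold for the flag column.
#' @return as [correlate_with_score()], one row per gene.
#' @export
correlate_with_genes <- function(mirna, mrna_expr, gene_list, flag_p = 1e-4) {
  validate_matrix(mrna_expr)
  genes <- intersect(gene_list, rownames(mrna_expr))
  if (length(genes) == 0L)
    return(data.frame(feature = character(0), rho = numeric(0),
                      p_value = numeric(0), n = integer(0),
                      defined = logical(0), skipped = logical(0),
                      q_value = numeric(0), flagged = logical(0)))
  correlate_rows(mrna_expr[genes, , drop = FALSE], mirna, flag_p = flag_p)
}

#' Correlate one miRNA with per-probe tracks (methylation, copy number)
#'
#' Generic per-track Spearman layer: each row of `tracks` (e.g. methylation
#' beta values per probe, or copy-number segments) is correlated with the
#' miRNA over complete pairs. Probes with fewer than 3 complete pairs are
#' reported with `skipped = TRUE` rather than dropped silently.
#'
#' @param mirna named per-sample expression vector.
#' @param tracks numeric matrix, probes x samples (missing values allowed).
#' @param flag_p nominal p-value threshold for the flag column.
#' @return as [correlate_with_score()], one row per probe.
#' @export
correlate_methylation <- function(mirna, tracks, flag_p = 1e-4) {
  validate_matrix(tracks)
  correlate_rows(tracks, mirna, flag_p = flag_p)
}
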