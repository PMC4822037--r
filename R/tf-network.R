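# Transcription-factor cascade: TFs predicted (at a matrix-similarity score
# cutoff) to bind the promoters of strictly more than `min_genes` panel
# genes, intersected with TFs predicted as direct miRNA targets by at least
# `min_algorithms` prediction algorithms. Both filters are anti-monotone in
# their thresholds, and all operations have set semantics (input row order
# never matters).

#' Validate a TF-binding prediction table
#'
#' @param binding data.frame with columns `tf`, `gene`, `matrix_similarity`
#'   (scores in [0, 1]). Duplicate (tf, gene) pairs are collapsed to the
#'   maximum score, with a message.
#' @return the validated, deduplicated table.
#' @export
as_tf_binding <- function(binding) {
  need <- c("tf", "gene", "matrix_similarity")
  miss <- setdiff(need, names(binding))
  if (length(miss))
    stop("TF binding table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- binding$matrix_similarity
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0 | s > 1))
    stop_field("matrix_similarity", "scores must lie in [0, 1]")
  key <- paste(binding$tf, binding$gene, sep = "\r")
  if (anyDuplicated(key)) {
    message("collapsing ", sum(duplicated(key)),
            " duplicate (tf, gene) pair(s) to their maximum score")
    o <- order(key, -s)
    binding <- binding[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  }
  binding
}

#' Validate a miRNA-target prediction table
#'
#' @param targets data.frame with columns `mirna`, `gene`, `algorithm`,
#'   `predicted` (logical); (mirna, gene, algorithm) triples must be unique.
#' @param algorithms declared algorithm vocabulary; defaults to the common
#'   sequence-based predictors.
#' @return the validated table.
#' @export
as_mir_targets <- function(targets,
                           algorithms = c("miRanda", "TargetScan", "PITA",
                                          "RNA22", "microT", "PicTar")) {
  need <- c("mirna", "gene", "algorithm", "predicted")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("miRNA target table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(targets$algorithm), algorithms)
  if (length(bad))
    stop_field("algorithm", paste("unknown algorithm(s):",
                                  paste(bad, collapse = ", ")))
  if (!is.logical(targets$predicted))
    stop_field("predicted", "must be logical")
  key <- paste(targets$mirna, targets$gene, targets$algorithm, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (mirna, gene, algorithm) row(s)", call. = FALSE)
  targets
}

#' Filter TFs by predicted binding to angiogenic-gene promoters
#'
#' Per TF, counts the distinct panel genes bound with matrix similarity at
#' least `min_score`; the TF passes when the count strictly exceeds
#' `min_genes`.
#'
#' @param binding TF-binding table (see [as_tf_binding()]).
#' @param angio_genes character vector of angiogenic panel genes.
#' @param min_score matrix-similarity cutoff, applied as `>= min_score`
#'   (default 0.9).
#' @param min_genes the count a TF must strictly exceed (default 5, i.e.
#'   "more than five"). Use 0 with a single-gene panel for a
#'   single-promoter scan.
#' @return data.frame, one row per TF appearing in the table, columns `tf`,
#'   `n_angio_targets`, `passes_binding`, sorted by tf; the surviving
#'   (tf, gene, score) edges are attached as the `"edges"` attribute.
#' @export
filter_tf_by_binding <- function(binding, angio_genes, min_score = 0.9,
                                 min_genes = 5) {
  binding <- as_tf_binding(binding)
  angio_genes <- as_gene_panel(angio_genes)
  hit <- binding[binding$gene %in% angio_genes &
                   binding$matrix_similarity >= min_score, , drop = FALSE]
  tfs <- sort(unique(binding$tf))
  counts <- vapply(tfs, function(tf)
    length(unique(hit$gene[hit$tf == tf])), integer(1))
  res <- data.frame(tf = tfs, n_angio_targets = unname(counts),
                    passes_binding = unname(counts) > min_genes,
                    stringsAsFactors = FALSE)
  edges <- hit[hit$tf %in% res$tf[res$passes_binding], , drop = FALSE]
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  structure(res, edges = edges)
}

#' Intersect binding candidates with miRNA-target predictions
#'
#' Per candidate TF, counts the distinct algorithms predicting the TF as a
#' direct target of `mirna`; the TF passes targeting when the count is at
#' least `min_algorithms`. The final candidates are those passing both
#' filters.
#'
#' @param candidates output of [filter_tf_by_binding()].
#' @param targets miRNA-target table (see [as_mir_targets()]).
#' @param mirna the miRNA of interest; if absent from the table all counts
#'   are 0 (with a warning).
#' @param min_algorithms inclusive algorithm-count threshold (default 4,
#'   i.e. "at least four").
#' @return the candidate table with added `supporting_algorithms`,
#'   `passes_targeting` and `passes` columns; surviving edges (restricted
#'   to final candidates) kept in the `"edges"` attribute.
#' @export
filter_by_mir_targeting <- function(candidates, targets, mirna,
                                    min_algorithms = 4) {
  targets <- as_mir_targets(targets)
  hits <- targets[targets$mirna == mirna & targets$predicted, , drop = FALSE]
  if (!mirna %in% targets$mirna)
    warning("miRNA '", mirna, "' absent from target table; all counts are 0",
            call. = FALSE)
  support <- vapply(candidates$tf, function(tf)
    length(unique(hits$algorithm[hits$gene == tf])), integer(1))
  candidates$supporting_algorithms <- unname(support)
  candidates$passes_targeting <- candidates$supporting_algorithms >=
    min_algorithms
  candidates$passes <- candidates$passes_binding & candidates$passes_targeting
  edges <- attr(candidates, "edges")
  if (!is.null(edges))
    attr(candidates, "edges") <-
      edges[edges$tf %in% candidates$tf[candidates$passes], , drop = FALSE]
  candidates
}

#' Bipartite TF-gene edge list for the final candidates
#'
#' @param final_candidates output of [filter_by_mir_targeting()].
#' @return data.frame `tf`, `gene`, `matrix_similarity`, sorted by tf then
#'   gene (deterministic; duplicates already collapsed to max score).
#' @export
build_bipartite_edges <- function(final_candidates) {
  edges <- attr(final_candidates, "edges")
  if (is.null(edges) || nrow(edges) == 0L)
    return(data.frame(tf = character(0), gene = character(0),
                      matrix_similarity = numeric(0)))
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  edges[, c("tf", "gene", "matrix_similarity")]
}
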