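# End-to-end discovery pipeline: MVD median-decrease screen -> correlation
# with the angiogenesis score -> optimal-percentile survival scan, with an
# optional transcription-factor cascade on the shortlist. Each stage is the
# exported stage function with the same parameters; the orchestrator adds no
# hidden state, so its counts always equal the row counts of the per-stage
# outputs.

#' Run the integrative miRNA discovery screen
#'
#' Stage order: (1) median-decrease screen of miRNA counts between high- and
#' low-MVD tumours; (2) Spearman correlation of the screen survivors with
#' the per-sample pro-angiogenic signature score, keeping features whose
#' correlation points in the direction of interest with nominal p below
#' `corr_p`; (3) optimal-percentile log-rank cutpoint scan of each survivor
#' against overall survival, keeping flagged features. The shortlist is the
#' set passing all stages.
#'
#' @param mirna_expr miRNA count matrix (miRNAs x samples).
#' @param mrna_expr mRNA expression matrix for the signature score.
#' @param panel pro-angiogenic gene panel (character vector).
#' @param mvd MVD table (`sample`, `vessels_per_hpf`).
#' @param clinical clinical table (`sample`, `time`, `event`).
#' @param decrease_threshold screen decrease threshold (default 0.8).
#' @param mvd_high,mvd_low vessel-count group cutoffs (defaults 36/16).
#' @param corr_p correlation-stage nominal p threshold (default 1e-4).
#' @param direction "down" keeps negative correlations (miRNAs low when the
#'   score is high), "up" positive, "both" either.
#' @param scan_lo,scan_hi,scan_step,alpha cutpoint-scan grid and flag level.
#' @param n_perm permutations for the scan's adjusted p (0 = nominal only).
#' @param use_adjusted_p flag the survival stage on the permutation-adjusted
#'   p instead of the nominal minimum p (requires `n_perm` > 0).
#' @param require_protective keep only features whose high-expression group
#'   has better survival (direction-of-effect filter; default off).
#' @param tf_binding,tf_targets,tf_mirna optional TF-cascade inputs; when
#'   supplied, the cascade is run with `tf_min_score`, `tf_min_genes`,
#'   `tf_min_algorithms`.
#' @param tf_min_score,tf_min_genes,tf_min_algorithms cascade thresholds
#'   (defaults 0.9, 5, 4).
#' @return a `pipeline_report` list: per-stage tables (`screen`,
#'   `correlation`, `survival`, optionally `tf`), `shortlist`, `counts`
#'   (with the thresholds that produced them recorded beside each count)
#'   and `parameters`.
#' @export
run_screen <- function(mirna_expr, mrna_expr, panel, mvd, clinical,
                       decrease_threshold = 0.8, mvd_high = 36, mvd_low = 16,
                       corr_p = 1e-4, direction = c("down", "up", "both"),
                       scan_lo = 0.25, scan_hi = 0.75, scan_step = 0.01,
                       alpha = 0.05, n_perm = 0L, use_adjusted_p = FALSE,
                       require_protective = FALSE,
                       tf_binding = NULL, tf_targets = NULL, tf_mirna = NULL,
                       tf_min_score = 0.9, tf_min_genes = 5,
                       tf_min_algorithms = 4) {
  direction <- match.arg(direction)
  if (use_adjusted_p && n_perm <= 0L)
    stop("use_adjusted_p requires n_perm > 0", call. = FALSE)

  # stage 1: MVD extremes + median-decrease screen
  groups <- assign_mvd_groups(mvd, high_threshold = mvd_high,
                              low_threshold = mvd_low)
  screen <- median_decrease_screen(mirna_expr, groups,
                                   decrease_threshold = decrease_threshold)
  survivors <- screen$mirna[screen$passes]

  # stage 2: correlation with the signature score
  scores <- angiogenesis_score(mrna_expr, panel)
  correlation <- NULL
  corr_pass <- character(0)
  if (length(survivors) > 0) {
    correlation <- correlate_with_score(
      mirna_expr[survivors, , drop = FALSE], scores, flag_p = corr_p)
    dir_ok <- switch(direction,
                     down = correlation$rho < 0,
                     up = correlation$rho > 0,
                     both = rep(TRUE, nrow(correlation)))
    keep <- correlation$defined & !correlation$skipped &
      correlation$p_value < corr_p & dir_ok
    corr_pass <- correlation$feature[keep]
  }

  # stage 3: survival cutpoint scan
  surv_rows <- list()
  surv_pass <- character(0)
  for (f in corr_pass) {
    scan <- cutpoint_scan(mirna_expr[f, ], clinical, lo = scan_lo,
                          hi = scan_hi, step = scan_step, alpha = alpha,
                          n_perm = n_perm)
    flagged <- if (use_adjusted_p) scan$adjusted_p < alpha else scan$flagged
    protective <- NA
    if (flagged && require_protective) {
      split <- dichotomize_at_percentile(mirna_expr[f, names(scores)],
                                         scan$optimal_percentile)
      cl <- clinical
      km_high <- km_estimate(cl[cl$sample %in% split$high, , drop = FALSE])
      km_low <- km_estimate(cl[cl$sample %in% split$low, , drop = FALSE])
      protective <- mean_survival(km_high) > mean_survival(km_low)
      flagged <- flagged && protective
    }
    surv_rows[[f]] <- data.frame(
      mirna = f, optimal_percentile = scan$optimal_percentile,
      optimal_p = scan$optimal_p, adjusted_p = scan$adjusted_p,
      flagged = flagged, protective = protective, stringsAsFactors = FALSE)
    if (flagged) surv_pass <- c(surv_pass, f)
  }
  survival_tab <- if (length(surv_rows)) do.call(rbind, surv_rows) else
    data.frame(mirna = character(0), optimal_percentile = numeric(0),
               optimal_p = numeric(0), adjusted_p = numeric(0),
               flagged = logical(0), protective = logical(0))
  rownames(survival_tab) <- NULL

  # optional stage 4: TF cascade
  tf_tab <- NULL
  if (!is.null(tf_binding) && !is.null(tf_targets) && !is.null(tf_mirna)) {
    cand <- filter_tf_by_binding(tf_binding, panel, min_score = tf_min_score,
                                 min_genes = tf_min_genes)
    tf_tab <- filter_by_mir_targeting(cand, tf_targets, tf_mirna,
                                      min_algorithms = tf_min_algorithms)
  }

  report <- list(
    parameters = list(
      decrease_threshold = decrease_threshold, mvd_high = mvd_high,
      mvd_low = mvd_low, corr_p = corr_p, direction = direction,
      scan_lo = scan_lo, scan_hi = scan_hi, scan_step = scan_step,
      alpha = alpha, n_perm = n_perm, use_adjusted_p = use_adjusted_p,
      require_protective = require_protective,
      tf_min_score = tf_min_score, tf_min_genes = tf_min_genes,
      tf_min_algorithms = tf_min_algorithms),
    screen = screen, correlation = correlation, survival = survival_tab,
    tf = tf_tab,
    counts = list(
      n_mirnas = nrow(mirna_expr),
      n_screen_pass = list(count = length(survivors),
                           threshold = decrease_threshold),
      n_correlation_pass = list(count = length(corr_pass),
                                threshold = corr_p),
      n_survival_pass = list(count = length(surv_pass), threshold = alpha),
      n_tf_candidates = if (is.null(tf_tab)) NULL else
        list(count = sum(tf_tab$passes),
             threshold = c(score = tf_min_score, genes = tf_min_genes,
                           algorithms = tf_min_algorithms))),
    shortlist = surv_pass,
    version = as.character(utils::packageVersion("angiomir")))
  class(report) <- "pipeline_report"
  report
}

# restricted-mean survival from a KM staircase (for the protective flag)
mean_survival <- function(km) {
  t <- c(0, km$time)
  s <- c(1, km$surv)
  sum(diff(t) * s[-length(s)])
}

#' Serialize a pipeline report to a directory
#'
#' Writes per-stage TSVs plus `report.json`. Given identical inputs the
#' output is byte-identical (no timestamps in the report).
#'
#' @param report a [run_screen()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$screen, file.path(dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$correlation))
    utils::write.table(report$correlation, file.path(dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$tf))
    utils::write.table(report$tf, file.path(dir, "tf_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(parameters = report$parameters, counts = report$counts,
               shortlist = report$shortlist, version = report$version)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
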