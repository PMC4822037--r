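# Discovery filter: miRNAs whose median expression collapses in highly
# angiogenic (high microvessel-density) tumours.

#' Assign tumours to extreme microvessel-density groups
#'
#' Samples strictly above `high_threshold` vessels per high-power field are
#' "high", strictly below `low_threshold` are "low", everything else
#' (including samples exactly at a threshold) is "excluded".
#'
#' @param mvd data.frame with columns `sample` and `vessels_per_hpf`.
#' @param high_threshold,low_threshold vessel-count cutoffs (defaults 36/16).
#' @return the input with a `group` factor column (high/low/excluded); group
#'   counts are reported with \code{message()}.
#' @export
assign_mvd_groups <- function(mvd, high_threshold = 36, low_threshold = 16) {
  if (!all(c("sample", "vessels_per_hpf") %in% names(mvd)))
    stop("mvd table needs columns 'sample' and 'vessels_per_hpf'",
         call. = FALSE)
  if (low_threshold > high_threshold)
    stop_field("low_threshold", "must not exceed high_threshold")
  v <- mvd$vessels_per_hpf
  if (any(!is.finite(v)) || any(v < 0))
    stop_field("vessels_per_hpf", "vessel counts must be finite and >= 0")
  group <- rep("excluded", length(v))
  group[v > high_threshold] <- "high"
  group[v < low_threshold] <- "low"
  mvd$group <- factor(group, levels = c("high", "low", "excluded"))
  counts <- table(mvd$group)
  message(sprintf("MVD groups: high n=%d, low n=%d, excluded n=%d",
                  counts[["high"]], counts[["low"]], counts[["excluded"]]))
  mvd
}

#' Median-decrease screen between high- and low-MVD groups
#'
#' For each miRNA, computes the median expression in the high- and low-MVD
#' groups and the decrease fraction `1 - median_high/median_low`. A miRNA
#' passes when its median drops by strictly more than `decrease_threshold`
#' in the high group, i.e. `median_high/median_low < 1 - decrease_threshold`
#' (at the default 0.8: ratio < 0.2). The screen works on group medians, so
#' it is invariant to rescaling all counts by a positive constant.
#'
#' @param expr non-negative expression matrix (e.g. normalized counts),
#'   miRNAs x samples.
#' @param groups output of [assign_mvd_groups()]; only samples in the
#'   high/low groups and present in `expr` are used.
#' @param decrease_threshold required decrease fraction (default 0.8).
#' @param scale either "none" (default) or "total": "total" rescales each
#'   sample to the mean library size first (the pass/fail outcome is
#'   unaffected by a global rescaling, but per-group medians are reported on
#'   the chosen scale).
#' @return data.frame, one row per miRNA, columns `mirna`, `median_high`,
#'   `median_low`, `decrease` (NA when `median_low` is 0) and `passes`,
#'   sorted by decrease descending (NAs last, ties by name).
#' @export
median_decrease_screen <- function(expr, groups, decrease_threshold = 0.8,
                                   scale = c("none", "total")) {
  validate_matrix(expr, allow_missing = FALSE)
  scale <- match.arg(scale)
  if (any(expr < 0))
    stop("expression must be non-negative counts", call. = FALSE)
  check_scalar_number(decrease_threshold, "decrease_threshold",
                      nonnegative = TRUE)
  if (!"group" %in% names(groups))
    stop("groups must come from assign_mvd_groups()", call. = FALSE)
  high <- intersect(groups$sample[groups$group == "high"], colnames(expr))
  low <- intersect(groups$sample[groups$group == "low"], colnames(expr))
  if (length(high) == 0L || length(low) == 0L)
    stop("both MVD groups must be non-empty among matrix samples",
         call. = FALSE)
  if (scale == "total") {
    libsize <- colSums(expr)
    if (any(libsize == 0))
      stop("cannot total-count scale a sample with zero counts", call. = FALSE)
    expr <- sweep(expr, 2L, libsize / mean(libsize), "/")
  }
  med_high <- apply(expr[, high, drop = FALSE], 1L, stats::median)
  med_low <- apply(expr[, low, drop = FALSE], 1L, stats::median)
  decrease <- ifelse(med_low > 0, 1 - med_high / med_low, NA_real_)
  passes <- !is.na(decrease) & med_high < (1 - decrease_threshold) * med_low
  undef <- which(is.na(decrease))
  if (length(undef))
    message("decrease undefined (zero low-group median) for: ",
            paste(rownames(expr)[undef], collapse = ", "))
  out <- data.frame(mirna = rownames(expr), median_high = med_high,
                    median_low = med_low, decrease = decrease,
                    passes = passes, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$decrease, out$mirna, na.last = TRUE), , drop = FALSE]
}
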