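# Kaplan-Meier estimation, log-rank testing and the optimal-percentile
# cutpoint scan.
#
# The scan dichotomizes a continuous marker at every percentile on a grid
# (default 0.25..0.75 step 0.01, 51 points), runs an unweighted two-group
# log-rank test at each split and reports the split with the smallest
# nominal p-value. Minimum-p selection is anti-conservative, so a
# permutation-adjusted p-value (marker values permuted against the survival
# records, whole scan re-run) is available alongside the nominal one; it is
# reported separately, never substituted.

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over \code{survival::survfit} returning the staircase in a
#' plain list. Censored records tied with an event time are counted at risk
#' for that event (the standard convention: censoring after events).
#'
#' @param records data.frame with columns `time` (> 0) and `event` (0/1).
#' @return list with `time`, `surv`, `n_risk`, `n_event`, `n_censor`
#'   (one entry per distinct observed time, events and censorings).
#' @export
km_estimate <- function(records) {
  records <- as_clinical_like(records)
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1, conf.type = "none")
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, n_censor = fit$n.censor)
}

# Accept either a full clinical table or a bare time/event frame.
as_clinical_like <- function(records) {
  if (!all(c("time", "event") %in% names(records)))
    stop("records need 'time' and 'event' columns", call. = FALSE)
  if (any(records$time <= 0)) stop_field("time", "must be > 0")
  if (!all(records$event %in% c(0, 1)))
    stop_field("event", "must be 0 or 1")
  records
}

# Precompute the risk-set structure of one survival dataset so that the
# log-rank chi-square can be evaluated cheaply for many group labellings
# (grid percentiles, permutations). Returns a closure: chisq(group01).
logrank_engine <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  # block = run of tied times; risk set at a block = everyone from its start
  first <- !duplicated(time)
  block_start <- which(first)                  # index of first member
  block_id <- cumsum(first)                    # block index per position
  n_blocks <- length(block_start)
  at_risk <- n - block_start + 1L              # n_i per block
  d <- as.vector(rowsum(event, block_id))      # total deaths per block
  keep <- d > 0 & at_risk > 1L                 # blocks contributing to V
  keep_any <- d > 0
  list(
    order = ord,
    n_events = sum(event),
    chisq = function(group01) {
      g <- group01[ord]
      # at risk in group A at each block start: suffix sums of g
      sfx <- rev(cumsum(rev(g)))
      n1 <- sfx[block_start]
      d1 <- as.vector(rowsum(event * g, block_id))
      o <- sum(d1[keep_any])
      e <- sum(d[keep_any] * n1[keep_any] / at_risk[keep_any])
      v <- sum(d[keep] * (n1[keep] / at_risk[keep]) *
                 (1 - n1[keep] / at_risk[keep]) *
                 (at_risk[keep] - d[keep]) / (at_risk[keep] - 1L))
      if (v <= 0) return(NA_real_)
      (o - e)^2 / v
    })
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank: at each distinct event time the observed
#' group-A events are compared with the hypergeometric expectation; the
#' chi-square is (O_A - E_A)^2 / V on 1 degree of freedom.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns.
#' @return list with `chisq`, `p_value`, `observed` and `expected` (length-2,
#'   groups A and B) and `defined` (FALSE when there are no events or no
#'   variance, in which case the statistic is NA and flagged).
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as_clinical_like(group_a)
  group_b <- as_clinical_like(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  g <- rep(c(1, 0), c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0L)
    return(list(chisq = NA_real_, p_value = NA_real_,
                observed = c(A = 0, B = 0), expected = c(A = NA, B = NA),
                defined = FALSE))
  eng <- logrank_engine(time, event)
  chisq <- eng$chisq(g)
  # observed/expected per group for reporting
  oe <- logrank_oe(time, event, g)
  if (is.na(chisq))
    return(list(chisq = NA_real_, p_value = NA_real_, observed = oe$observed,
                expected = oe$expected, defined = FALSE))
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = oe$observed, expected = oe$expected, defined = TRUE)
}

logrank_oe <- function(time, event, g) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g <- g[ord]
  n <- length(time)
  first <- !duplicated(time)
  block_start <- which(first)
  block_id <- cumsum(first)
  at_risk <- n - block_start + 1L
  d <- as.vector(rowsum(event, block_id))
  sfx <- rev(cumsum(rev(g)))
  n1 <- sfx[block_start]
  d1 <- as.vector(rowsum(event * g, block_id))
  keep <- d > 0
  oA <- sum(d1[keep]); eA <- sum(d[keep] * n1[keep] / at_risk[keep])
  oTot <- sum(d[keep])
  c_list <- list(observed = c(A = oA, B = oTot - oA),
                 expected = c(A = eA, B = oTot - eA))
  c_list
}

#' Dichotomize samples at a percentile of a marker
#'
#' The split point is the linear-interpolation quantile (R's default type 7)
#' of the values; samples with value less than or equal to the quantile go
#' to the low group, the rest to the high group.
#'
#' @param values named numeric vector (names = sample ids), length >= 2.
#' @param percentile split percentile in (0, 1).
#' @return list with `low`, `high` (sample id vectors) and `defined`
#'   (FALSE when the values are all identical or either group is empty).
#' @export
dichotomize_at_percentile <- function(values, percentile) {
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (percentile <= 0 || percentile >= 1)
    stop_field("percentile", "must lie strictly inside (0, 1)")
  if (length(unique(values)) == 1L)
    return(list(low = character(0), high = character(0), defined = FALSE))
  q <- stats::quantile(values, probs = percentile, type = 7, names = FALSE)
  low <- names(values)[values <= q]
  high <- names(values)[values > q]
  if (length(low) == 0L || length(high) == 0L)
    return(list(low = low, high = high, defined = FALSE))
  list(low = low, high = high, defined = TRUE)
}

#' Optimal-percentile log-rank cutpoint scan
#'
#' Evaluates the two-group log-rank test at every percentile of the marker
#' on a grid (defaults: 0.25 to 0.75 in steps of 0.01, i.e. 51 splits) and
#' reports the split with the smallest nominal p-value; ties in p are broken
#' toward the smaller percentile. Because taking the minimum over many
#' correlated tests inflates nominal significance, a permutation-adjusted
#' p-value can be requested: the marker values are permuted against the
#' survival records `n_perm` times, the whole scan re-run, and the adjusted
#' p is the rank of the observed minimum p among the permuted minima.
#'
#' @param values named numeric marker vector (names = sample ids).
#' @param records data.frame with `sample`, `time`, `event`.
#' @param lo,hi,step percentile grid (defaults 0.25, 0.75, 0.01).
#' @param alpha nominal flag level (default 0.05) applied to the optimal p.
#' @param n_perm number of whole-scan permutations for the adjusted p
#'   (0 = skip).
#' @return list with `percentiles`, `p_values` (NA where no valid split),
#'   `chisq`, `optimal_percentile`, `optimal_p`, `flagged`
#'   (optimal_p < alpha), `adjusted_p` (NA when `n_perm` = 0) and
#'   `quantile_type` metadata.
#' @export
cutpoint_scan <- function(values, records, lo = 0.25, hi = 0.75, step = 0.01,
                          alpha = 0.05, n_perm = 0L) {
  records <- as_clinical_like(records)
  if (!"sample" %in% names(records))
    stop("records need a 'sample' column", call. = FALSE)
  shared <- intersect(names(values), records$sample)
  if (length(shared) < 2L)
    stop("values and records share fewer than 2 samples", call. = FALSE)
  values <- values[shared]
  records <- records[match(shared, records$sample), , drop = FALSE]
  grid <- seq(lo, hi, by = step)
  if (length(grid) == 0L) stop("empty percentile grid", call. = FALSE)
  n <- length(values)

  eng <- logrank_engine(records$time, records$event)
  # group-A (low) membership depends only on how many values fall at or
  # below each grid quantile; under permutation of the values the quantiles
  # are unchanged (same multiset), so permutations only permute ranks.
  qs <- stats::quantile(values, probs = grid, type = 7, names = FALSE)
  m <- vapply(qs, function(q) sum(values <= q), integer(1))
  r <- rank(values, ties.method = "first")

  scan_once <- function(rk) {
    vapply(m, function(mk) {
      if (mk == 0L || mk == n) return(NA_real_)
      eng$chisq(as.numeric(rk <= mk))
    }, numeric(1))
  }
  chisq <- if (length(unique(values)) == 1L) rep(NA_real_, length(grid))
           else scan_once(r)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (all(is.na(p)))
    stop("no valid split anywhere on the percentile grid", call. = FALSE)
  best <- which(p == min(p, na.rm = TRUE))[1L]  # ties -> smaller percentile
  optimal_p <- p[best]

  adjusted_p <- NA_real_
  if (n_perm > 0L) {
    perm_min <- vapply(seq_len(n_perm), function(i) {
      pk <- scan_once(sample.int(n))
      min(stats::pchisq(pk, df = 1, lower.tail = FALSE), na.rm = TRUE)
    }, numeric(1))
    adjusted_p <- (1 + sum(perm_min <= optimal_p)) / (n_perm + 1)
  }
  list(percentiles = grid, p_values = p, chisq = chisq,
       optimal_percentile = grid[best], optimal_p = optimal_p,
       flagged = optimal_p < alpha, adjusted_p = adjusted_p,
       n_perm = n_perm, quantile_type = 7L)
}
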