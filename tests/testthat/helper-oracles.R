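# Independent oracles and small fixture builders shared across tests.
# Each oracle re-derives its quantity by the most direct route available
# (explicit ranks, loops, permutation, dense linear algebra), independent of
# the implementation it checks.

# Spearman rho/p by explicit mid-ranks + Pearson + t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  r <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Signature score by plain loops: median per gene, +/-1 signs, mean.
oracle_score <- function(mat, panel) {
  scores <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    total <- 0
    for (g in panel) {
      med <- stats::median(mat[g, ])
      total <- total + if (mat[g, s] > med) 1 else -1
    }
    scores[s] <- total / length(panel)
  }
  stats::setNames(scores, colnames(mat))
}

# Quantile normalization by explicit sort-mean-reassign (tie-free input).
oracle_quantile_normalize <- function(mat) {
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- ref[rank(mat[, j])]
  out
}

# Log-rank chi-square by an explicit loop over distinct event times.
oracle_logrank_chisq <- function(time, event, group01) {
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group01 == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group01 == 1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Permutation p-value for the log-rank test (relabelling the pooled data).
oracle_logrank_perm_p <- function(time, event, group01, n_perm = 2000L) {
  eng <- angiomir:::logrank_engine(time, event)
  obs <- eng$chisq(group01)
  perm <- vapply(seq_len(n_perm), function(i) eng$chisq(sample(group01)),
                 numeric(1))
  mean(perm >= obs)
}

# Random survival dataset with at least one event.
random_clinical <- function(n, censor_frac = 0.3) {
  repeat {
    df <- data.frame(sample = sprintf("s%03d", seq_len(n)),
                     time = stats::rexp(n, rate = 0.2),
                     event = as.integer(stats::runif(n) > censor_frac),
                     stringsAsFactors = FALSE)
    if (sum(df$event) >= 2) return(df)
  }
}

# Random tie-free expression matrix with dimnames.
random_matrix <- function(n_feat, n_samp) {
  m <- matrix(stats::rnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}
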