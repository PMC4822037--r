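test_that("KM estimate matches the closed-form staircase without censoring", {
  km <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  all_cens <- km_estimate(data.frame(time = c(1, 2, 3), event = 0))
  expect_true(all(all_cens$surv == 1))
  withr::local_seed(21)
  for (i in 1:5) {
    n <- sample(3:12, 1)
    km <- km_estimate(data.frame(time = sort(runif(n)) * 10, event = 1))
    expect_equal(km$surv, 1 - seq_len(n) / n)
  }
  expect_error(km_estimate(data.frame(time = numeric(0), event = numeric(0))),
               "no survival records")
})

test_that("censoring tied with an event time stays at risk for that event", {
  km <- km_estimate(data.frame(time = c(1, 1, 1), event = c(1, 1, 0)))
  expect_equal(km$surv, 1 / 3)
})

test_that("log-rank matches the hand-computed O/E/V worked example", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  res <- logrank_test(a, b)
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-12)  # O=2, E=5/6, V=17/36
  expect_equal(res$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_equal(unname(res$observed), c(2, 2))
  expect_equal(unname(res$expected), c(5 / 6, 4 - 5 / 6))
})

test_that("log-rank is zero for identical groups and symmetric under swap", {
  g <- data.frame(time = c(1, 3, 5, 7), event = c(1, 0, 1, 1))
  res <- logrank_test(g, g)
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)
  withr::local_seed(22)
  for (i in 1:10) {
    a <- random_clinical(sample(5:15, 1))
    b <- random_clinical(sample(5:15, 1))
    expect_equal(logrank_test(a, b)$chisq, logrank_test(b, a)$chisq,
                 tolerance = 1e-12)
  }
})

test_that("log-rank agrees with survdiff and the explicit-loop oracle", {
  withr::local_seed(23)
  for (i in 1:20) {
    a <- random_clinical(sample(5:20, 1))
    b <- random_clinical(sample(5:20, 1))
    res <- logrank_test(a, b)
    time <- c(a$time, b$time)
    event <- c(a$event, b$event)
    grp <- rep(c(1, 0), c(nrow(a), nrow(b)))
    expect_equal(res$chisq, oracle_logrank_chisq(time, event, grp),
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(res$chisq, sd$chisq, tolerance = 1e-10)
  }
})

test_that("zero events give a flagged-undefined log-rank result", {
  a <- data.frame(time = c(1, 2), event = 0)
  b <- data.frame(time = c(3, 4), event = 0)
  res <- logrank_test(a, b)
  expect_false(res$defined)
  expect_true(is.na(res$chisq))
})

test_that("percentile dichotomization uses linear-interpolation quantiles", {
  v <- setNames(1:10, letters[1:10])
  split <- dichotomize_at_percentile(v, 0.3)   # quantile(0.3) = 3.7
  expect_identical(split$low, c("a", "b", "c"))
  expect_length(split$high, 7)
  split5 <- dichotomize_at_percentile(v, 0.5)  # quantile(0.5) = 5.5
  expect_length(split5$low, 5)
  expect_length(split5$high, 5)
  const <- dichotomize_at_percentile(setNames(rep(1, 4), letters[1:4]), 0.5)
  expect_false(const$defined)
  expect_error(dichotomize_at_percentile(v, 1.2), "percentile")
})

test_that("the default scan grid has 51 percentiles and a valid optimum", {
  withr::local_seed(24)
  cl <- random_clinical(60)
  values <- setNames(rnorm(60), cl$sample)
  scan <- cutpoint_scan(values, cl)
  expect_length(scan$percentiles, 51)
  expect_equal(scan$optimal_p, min(scan$p_values, na.rm = TRUE))
  expect_true(scan$optimal_percentile %in% scan$percentiles)
  # optimal p never exceeds the median-split p
  expect_lte(scan$optimal_p, scan$p_values[scan$percentiles == 0.5])
  expect_identical(scan$flagged, scan$optimal_p < 0.05)
})

test_that("scan p-values equal stand-alone log-rank tests at each split", {
  withr::local_seed(25)
  cl <- random_clinical(40)
  values <- setNames(rnorm(40), cl$sample)
  scan <- cutpoint_scan(values, cl)
  for (k in c(1, 17, 34, 51)) {
    split <- dichotomize_at_percentile(values, scan$percentiles[k])
    res <- logrank_test(cl[cl$sample %in% split$low, , drop = FALSE],
                        cl[cl$sample %in% split$high, , drop = FALSE])
    expect_equal(scan$p_values[k], res$p_value, tolerance = 1e-12)
  }
})

test_that("p ties break toward the smaller percentile", {
  # two samples per side of every split: tiny n makes many splits identical
  cl <- data.frame(sample = sprintf("s%d", 1:6),
                   time = c(1, 2, 3, 4, 5, 6), event = 1)
  values <- setNames(c(6, 5, 4, 3, 2, 1), cl$sample)
  scan <- cutpoint_scan(values, cl)
  dup <- which(scan$p_values == scan$optimal_p)
  expect_identical(scan$optimal_percentile, scan$percentiles[dup[1]])
})

test_that("a constant marker admits no valid split anywhere on the grid", {
  cl <- random_clinical(10)
  values <- setNames(rep(1, 10), cl$sample)
  expect_error(cutpoint_scan(values, cl), "no valid split")
})

test_that("permutation-adjusted p exceeds the nominal minimum p under null", {
  withr::local_seed(26)
  cl <- random_clinical(50)
  values <- setNames(rnorm(50), cl$sample)
  scan <- cutpoint_scan(values, cl, n_perm = 100)
  expect_true(scan$adjusted_p >= scan$optimal_p)
  expect_true(scan$adjusted_p <= 1)
})

test_that("a marker equal to minus the latent activity is flagged", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(n_samples = 300,
                                        hazard_coupling = 1, seed = s))
    marker <- -co$latent_activity
    cutpoint_scan(marker, co$clinical)$flagged
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("with no hazard coupling, median-split log-rank p is calibrated", {
  ps <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_config(
      n_samples = 60, hazard_coupling = 0, n_null_mirnas = 0,
      n_meth_planted = 0, n_meth_null = 0, seed = s))
    marker <- co$mirna_expr["mir-planted-1", ]
    split <- dichotomize_at_percentile(marker, 0.5)
    cl <- co$clinical
    logrank_test(cl[cl$sample %in% split$low, , drop = FALSE],
                 cl[cl$sample %in% split$high, , drop = FALSE])$p_value
  }, numeric(1))
  expect_true(abs(mean(ps < 0.05) - 0.05) <= 0.04)
})
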