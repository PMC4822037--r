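panel20 <- sprintf("ANGIO%02d", 1:20)

binding_row <- function(tf, genes, score) {
  data.frame(tf = tf, gene = genes, matrix_similarity = score,
             stringsAsFactors = FALSE)
}

test_that("binding filter applies 'more than five genes' strictly", {
  binding <- rbind(binding_row("TF6", panel20[1:6], 0.95),
                   binding_row("TF5", panel20[1:5], 0.95),
                   binding_row("TF6low", panel20[1:6],
                               c(rep(0.95, 5), 0.89)))
  res <- filter_tf_by_binding(binding, panel20)
  expect_true(res$passes_binding[res$tf == "TF6"])
  expect_false(res$passes_binding[res$tf == "TF5"])     # 5 is not > 5
  expect_identical(res$n_angio_targets[res$tf == "TF6low"], 5L)
  expect_false(res$passes_binding[res$tf == "TF6low"])  # 0.89 edge dropped
  expect_error(filter_tf_by_binding(binding, character(0)), "empty")
})

test_that("score cutoff is inclusive and off-panel genes never count", {
  binding <- rbind(binding_row("TF", c(panel20[1:6], "OFFPANEL"), 0.9))
  res <- filter_tf_by_binding(binding, panel20)
  expect_identical(res$n_angio_targets, 6L)   # >= 0.9 kept, off-panel ignored
  expect_true(res$passes_binding)
})

test_that("duplicate (tf, gene) rows collapse to the maximum score", {
  binding <- rbind(binding_row("TF", panel20[1], 0.85),
                   binding_row("TF", panel20[1], 0.97),
                   binding_row("TF", panel20[2:6], 0.95))
  expect_message(dedup <- as_tf_binding(binding), "duplicate")
  expect_equal(
    dedup$matrix_similarity[dedup$gene == panel20[1]], 0.97)
  res <- suppressMessages(filter_tf_by_binding(binding, panel20))
  expect_identical(res$n_angio_targets, 6L)
})

test_that("targeting filter applies 'at least four algorithms' inclusively", {
  binding <- rbind(binding_row("TF4", panel20[1:6], 0.95),
                   binding_row("TF3", panel20[1:6], 0.95))
  targets <- rbind(
    data.frame(mirna = "miR-X", gene = "TF4",
               algorithm = c("miRanda", "TargetScan", "PITA", "RNA22"),
               predicted = TRUE),
    data.frame(mirna = "miR-X", gene = "TF3",
               algorithm = c("miRanda", "TargetScan", "PITA", "RNA22"),
               predicted = c(TRUE, TRUE, TRUE, FALSE)))
  cand <- filter_tf_by_binding(binding, panel20)
  res <- filter_by_mir_targeting(cand, targets, "miR-X")
  expect_true(res$passes[res$tf == "TF4"])     # exactly 4 passes
  expect_false(res$passes[res$tf == "TF3"])    # 3 predicted algorithms
  expect_identical(res$supporting_algorithms[res$tf == "TF3"], 3L)
  expect_warning(filter_by_mir_targeting(cand, targets, "miR-absent"),
                 "absent from target table")
})

test_that("row order never affects the cascade outcome", {
  withr::local_seed(41)
  tabs <- generate_tf_tables(panel20, seed = 3)
  shuffled_binding <- tabs$binding[sample(nrow(tabs$binding)), ]
  shuffled_targets <- tabs$targets[sample(nrow(tabs$targets)), ]
  run <- function(b, t) {
    cand <- filter_tf_by_binding(b, panel20)
    res <- filter_by_mir_targeting(cand, t, "mir-planted-1")
    rownames(res) <- NULL
    attr(res, "edges") <- NULL
    res
  }
  expect_equal(run(tabs$binding, tabs$targets),
               run(shuffled_binding, shuffled_targets))
})

test_that("raising thresholds never adds candidates", {
  tabs <- generate_tf_tables(panel20, seed = 5)
  passes_at <- function(ms, mg, ma) {
    cand <- filter_tf_by_binding(tabs$binding, panel20,
                                 min_score = ms, min_genes = mg)
    res <- filter_by_mir_targeting(cand, tabs$targets, "mir-planted-1",
                                   min_algorithms = ma)
    res$tf[res$passes]
  }
  base <- passes_at(0.9, 5, 4)
  expect_true(all(passes_at(0.95, 5, 4) %in% base))
  expect_true(all(passes_at(0.9, 6, 4) %in% base))
  expect_true(all(passes_at(0.9, 5, 5) %in% base))
})

test_that("bipartite edges are deterministic, sorted and deduplicated", {
  binding <- rbind(binding_row("TFB", panel20[c(2, 1)], 0.95),
                   binding_row("TFA", panel20[1:6], 0.92),
                   binding_row("TFB", panel20[3:6], 0.95))
  targets <- data.frame(mirna = "m", gene = c("TFA", "TFB"),
                        algorithm = rep(c("miRanda", "TargetScan",
                                          "PITA", "RNA22"), each = 2),
                        predicted = TRUE)
  cand <- filter_tf_by_binding(binding, panel20)
  final <- filter_by_mir_targeting(cand, targets, "m")
  edges <- build_bipartite_edges(final)
  expect_identical(edges$tf, sort(edges$tf))
  expect_false(any(duplicated(edges[c("tf", "gene")])))
  expect_identical(nrow(edges), 12L)

  none <- filter_by_mir_targeting(cand, targets, "m", min_algorithms = 5)
  expect_identical(nrow(build_bipartite_edges(none)), 0L)
})

test_that("the cascade recovers planted truth with no decoy leakage", {
  results <- vapply(1:50, function(s) {
    tabs <- generate_tf_tables(panel20, seed = s)
    cand <- filter_tf_by_binding(tabs$binding, panel20)
    res <- filter_by_mir_targeting(cand, tabs$targets, "mir-planted-1")
    found <- res$tf[res$passes]
    setequal(found, tabs$truth$planted)
  }, logical(1))
  expect_true(all(results))
})

test_that("generated TF tables are deterministic under the seed", {
  expect_identical(generate_tf_tables(panel20, seed = 11),
                   generate_tf_tables(panel20, seed = 11))
})
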