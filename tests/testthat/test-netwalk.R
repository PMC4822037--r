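path_net <- function(values = c(1, 2, 1)) {
  generate_network("path", n_nodes = length(values), values = values)
}

test_that("transition probabilities are neighbour-value proportional", {
  # star: hub g01 connected to g02 (value 1) and g03 (value 3)
  net <- gene_network(data.frame(id = c("g01", "g02", "g03"),
                                 value = c(1, 1, 3)),
                      data.frame(from = c("g01", "g01"),
                                 to = c("g02", "g03")))
  P <- build_transition(net)
  expect_equal(unname(P["g01", c("g02", "g03")]), c(0.25, 0.75))
  expect_equal(unname(P["g02", "g01"]), 1)   # single neighbour
  expect_equal(unname(rowSums(P)), rep(1, 3))

  even <- gene_network(data.frame(id = c("a", "b", "c"), value = c(2, 1, 1)),
                       data.frame(from = c("a", "a"), to = c("b", "c")))
  expect_equal(unname(build_transition(even)["a", c("b", "c")]), c(0.5, 0.5))
})

test_that("restart mixes in the data-value-proportional distribution", {
  net <- path_net(c(1, 2, 1))
  P <- build_transition(net, restart = 0.2)
  pi0 <- c(0.25, 0.5, 0.25)
  expect_equal(unname(P["g01", ]), 0.8 * c(0, 1, 0) + 0.2 * pi0)
  expect_equal(unname(rowSums(P)), rep(1, 3))
})

test_that("stationary scores solve the 3-node path fixture analytically", {
  res <- stationary_scores(path_net(c(1, 2, 1)))
  expect_equal(unname(res$scores), c(0.25, 0.5, 0.25), tolerance = 1e-8)
  expect_equal(sum(res$scores), 1, tolerance = 1e-12)
  expect_equal(res$lazy, 0.01)
})

test_that("k-regular graphs with uniform values score uniformly", {
  for (s in 1:3) {
    net <- generate_network("k_regular", n_nodes = 8, k = 3, seed = s)
    res <- stationary_scores(net)
    expect_equal(unname(res$scores), rep(1 / 8, 8), tolerance = 1e-8)
  }
})

test_that("power iteration agrees with the dense eigen-solution", {
  for (s in 1:5) {
    net <- generate_network("random", n_nodes = 8, seed = s)
    res <- stationary_scores(net)
    P <- build_transition(net)
    P_lazy <- 0.99 * P + 0.01 * diag(nrow(P))
    eig <- eigen(t(P_lazy))
    lead <- Re(eig$vectors[, which.max(Re(eig$values))])
    lead <- lead / sum(lead)
    expect_equal(unname(res$scores), lead, tolerance = 1e-8)
  }
})

test_that("scores are stationary and invariant to value rescaling", {
  net <- generate_network("random", n_nodes = 10, seed = 7)
  res <- stationary_scores(net)
  P <- build_transition(net)
  expect_lt(sum(abs(as.vector(res$scores %*% P) - res$scores)), 1e-8)
  scaled <- net
  scaled$value <- net$value * 123.4
  expect_equal(stationary_scores(scaled)$scores, res$scores,
               tolerance = 1e-8)
})

test_that("increasing a node's data value never lowers its own score", {
  for (s in 1:5) {
    net <- generate_network("random", n_nodes = 8, seed = s + 10)
    before <- stationary_scores(net)$scores
    boosted <- net
    boosted$value[3] <- boosted$value[3] * 3
    after <- stationary_scores(boosted)$scores
    expect_gte(after[3] + 1e-12, before[3])
  }
})

test_that("edge flux recovers analytic values and sums to one", {
  single <- gene_network(data.frame(id = c("a", "b"), value = c(1, 5)),
                         data.frame(from = "a", to = "b"))
  res <- stationary_scores(single)
  es <- edge_scores(single, res)
  expect_equal(es$score, 1)

  path <- path_net(c(1, 2, 1))
  es_path <- edge_scores(path, stationary_scores(path))
  expect_equal(es_path$score, c(0.5, 0.5), tolerance = 1e-8)

  star <- gene_network(data.frame(id = c("h", "x", "y", "z"), value = 1),
                       data.frame(from = "h", to = c("x", "y", "z")))
  es_star <- edge_scores(star, stationary_scores(star))
  expect_equal(es_star$score, rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(sum(es_star$score), 1, tolerance = 1e-12)
})

test_that("degenerate networks are rejected with clear errors", {
  expect_error(gene_network(data.frame(id = "a", value = 1),
                            data.frame(from = character(0),
                                       to = character(0))),
               "at least 2 nodes")
  expect_error(gene_network(data.frame(id = c("a", "b"), value = 1),
                            data.frame(from = "a", to = "a")),
               "self-loops")
  expect_error(gene_network(data.frame(id = c("a", "b"), value = 1),
                            data.frame(from = c("a", "b"), to = c("b", "a"))),
               "duplicate edge")
  iso <- gene_network(data.frame(id = c("a", "b", "c"), value = 1),
                      data.frame(from = "a", to = "b"))
  expect_error(stationary_scores(iso), "restart")
  expect_warning(
    gene_network(data.frame(id = c("a", "b"), value = c(1, -2)),
                 data.frame(from = "a", to = "b")),
    "floored")
})

test_that("generated networks are deterministic and well-formed", {
  n1 <- generate_network("random", n_nodes = 12, seed = 4)
  n2 <- generate_network("random", n_nodes = 12, seed = 4)
  expect_identical(n1, n2)
  expect_true(n1$connected)
  expect_true(all(n1$value > 0))
  expect_error(generate_network("path", n_nodes = 1), "n_nodes")
})
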