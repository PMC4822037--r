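# Random-walk network relevance scoring.
#
# Node "data values" (strictly positive weights, e.g. expression changes on
# a positive scale) set the walk's transition probabilities: from node i the
# walk moves to neighbour j with probability proportional to j's data value
# among i's neighbours. A node's relevance is its stationary visitation
# frequency; an edge's relevance is the stationary probability flux across
# it. A small lazy-walk stay probability guards against periodicity (e.g.
# bipartite graphs) without changing the stationary distribution.

#' Construct a node-weighted undirected gene network
#'
#' @param nodes data.frame with columns `id` (unique) and `value`
#'   (data values; non-positive values are floored to 1e-6 of the positive
#'   median, with a warning).
#' @param edges data.frame with columns `from`, `to` referencing node ids;
#'   self-loops and duplicate edges are rejected.
#' @return list with `id`, `value`, `edges` (2-column character matrix) and
#'   `connected` flag.
#' @export
gene_network <- function(nodes, edges) {
  if (!all(c("id", "value") %in% names(nodes)))
    stop("nodes need 'id' and 'value' columns", call. = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges need 'from' and 'to' columns", call. = FALSE)
  id <- as.character(nodes$id)
  if (anyDuplicated(id))
    stop("duplicate node id: ", id[duplicated(id)][1L], call. = FALSE)
  if (length(id) < 2L) stop("need at least 2 nodes", call. = FALSE)
  value <- as.numeric(nodes$value)
  if (any(!is.finite(value))) stop_field("value", "must be finite")
  if (any(value <= 0)) {
    floor_val <- 1e-6 * stats::median(value[value > 0])
    if (!is.finite(floor_val))
      stop_field("value", "all node data values are non-positive")
    warning(sum(value <= 0), " non-positive node value(s) floored to ",
            format(floor_val), call. = FALSE)
    value[value <= 0] <- floor_val
  }
  a <- as.character(edges$from); b <- as.character(edges$to)
  bad <- setdiff(c(a, b), id)
  if (length(bad))
    stop("edge references unknown node: ", bad[1L], call. = FALSE)
  if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edge", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b), directed = FALSE,
    vertices = data.frame(name = id))
  list(id = id, value = stats::setNames(value, id),
       edges = cbind(from = a, to = b),
       connected = igraph::is_connected(g))
}

#' Neighbour-weighted transition matrix of the random walk
#'
#' From node i the probability of stepping to neighbour j is
#' `value(j) / sum(value(k), k in neighbours(i))`. With `restart > 0` the
#' rows are mixed with restart mass towards the data-value-proportional
#' distribution, making the chain irreducible on disconnected graphs.
#'
#' @param network a [gene_network()].
#' @param restart restart probability in [0, 1).
#' @return row-stochastic matrix (rows sum to 1), node ids as dimnames.
#' @export
build_transition <- function(network, restart = 0, .check = TRUE) {
  check_scalar_number(restart, "restart", nonnegative = TRUE)
  if (restart >= 1) stop_field("restart", "must be < 1")
  id <- network$id
  nn <- length(id)
  adj <- matrix(0, nn, nn, dimnames = list(id, id))
  adj[network$edges] <- 1
  adj[network$edges[, c(2, 1), drop = FALSE]] <- 1
  deg <- rowSums(adj)
  if (.check && any(deg == 0) && restart == 0)
    stop("isolated node '", id[which(deg == 0)[1L]],
         "' with restart = 0", call. = FALSE)
  if (.check && !network$connected && restart == 0)
    stop("network is disconnected; use restart > 0", call. = FALSE)
  w <- adj * rep(network$value, each = nn)   # w[i, j] = value(j) if edge
  rs <- rowSums(w)
  P <- w / ifelse(rs > 0, rs, 1)
  if (restart > 0) {
    pi0 <- network$value / sum(network$value)
    P <- (1 - restart) * P + restart * matrix(pi0, nn, nn, byrow = TRUE)
  }
  P
}

#' Stationary visitation frequencies of the random walk
#'
#' Power iteration to the stationary distribution of the transition rule.
#' When `restart = 0` a lazy-walk stay probability of 0.01 is mixed in so
#' that periodic (e.g. bipartite) graphs converge; laziness leaves the
#' stationary distribution unchanged. Scores are invariant to rescaling all
#' node data values by a positive constant.
#'
#' @param network a [gene_network()].
#' @param restart restart probability in [0, 1).
#' @param tol L1 convergence tolerance per iteration (default 1e-10).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last residual.
#' @return list with `scores` (named, >= 0, summing to 1), `iterations`,
#'   `residual` and `lazy` (the stay probability used).
#' @export
stationary_scores <- function(network, restart = 0, tol = 1e-10,
                              max_iter = 100000L) {
  P <- build_transition(network, restart = restart)
  lazy <- if (restart == 0) 0.01 else 0
  if (lazy > 0) P <- (1 - lazy) * P + lazy * diag(nrow(P))
  nn <- nrow(P)
  pi_vec <- rep(1 / nn, nn)
  for (it in seq_len(max_iter)) {
    nxt <- as.vector(pi_vec %*% P)
    resid <- sum(abs(nxt - pi_vec))
    pi_vec <- nxt
    if (resid < tol) {
      pi_vec <- pi_vec / sum(pi_vec)
      return(list(scores = stats::setNames(pi_vec, rownames(P)),
                  iterations = it, residual = resid, lazy = lazy))
    }
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %g)",
               max_iter, resid), call. = FALSE)
}

#' Stationary probability flux per edge
#'
#' The relevance of edge (i, j) is the stationary flux across it,
#' `pi_i P(i->j) + pi_j P(j->i)`, computed on the neighbour-following kernel
#' (no restart or laziness) and normalized to sum to 1 over edges.
#'
#' @param network a [gene_network()].
#' @param relevance output of [stationary_scores()].
#' @return data.frame `from`, `to`, `score`, in the network's edge order.
#' @export
edge_scores <- function(network, relevance) {
  P <- build_transition(network, restart = 0, .check = FALSE)
  pi_vec <- relevance$scores[rownames(P)]
  e <- network$edges
  flux <- pi_vec[e[, 1]] * P[e] + pi_vec[e[, 2]] * P[e[, c(2, 1), drop = FALSE]]
  flux <- flux / sum(flux)
  data.frame(from = e[, 1], to = e[, 2], score = unname(flux),
             stringsAsFactors = FALSE)
}
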