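test_that("absolutize takes connection magnitudes and drops the diagonal", {
  S <- matrix(c(1, -0.8, 0.3,
                -0.8, 1, 0.5,
                0.3, 0.5, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  g <- absolutize(S)
  expect_equal(g$weights["a", "b"], 0.8)
  expect_equal(diag(g$weights), setNames(rep(0, 3), letters[1:3]))
  # identity on positive entries, symmetry preserved
  expect_equal(g$weights["a", "c"], 0.3)
  expect_identical(g$weights, t(g$weights))
})

test_that("maximum spanning tree is forced on trees and exhaustively optimal", {
  # graph that already is a tree
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.7
  W[2, 4] <- W[4, 2] <- 0.2
  t1 <- maximum_spanning_tree(W)
  expect_equal(t1[order(t1[, 1], t1[, 2]), , drop = FALSE],
               cbind(i = c(1, 2, 2), j = c(2, 3, 4)), ignore_attr = TRUE)

  # 3-node triangle: enumeration of all 3 spanning trees picks {12, 13}
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.9
  W3[1, 3] <- W3[3, 1] <- 0.5
  W3[2, 3] <- W3[3, 2] <- 0.4
  t3 <- maximum_spanning_tree(W3)
  expect_equal(t3[order(t3[, 1], t3[, 2]), , drop = FALSE],
               cbind(i = c(1, 1), j = c(2, 3)), ignore_attr = TRUE)

  # equal weights everywhere: lexicographically smallest edge set
  We <- matrix(0.5, 3, 3); diag(We) <- 0
  te <- maximum_spanning_tree(We)
  expect_equal(te[order(te[, 1], te[, 2]), , drop = FALSE],
               cbind(i = c(1, 1), j = c(2, 3)), ignore_attr = TRUE)

  # random graphs: total weight matches the exhaustive-enumeration optimum
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    Wr <- random_weighted_graph(n)
    tr <- maximum_spanning_tree(Wr)
    idx <- which(upper.tri(Wr) & Wr > 0, arr.ind = TRUE)
    edges <- data.frame(i = idx[, 1], j = idx[, 2], w = Wr[idx])
    best <- oracle_max_spanning_tree(edges, n, seq_len(nrow(edges)))
    expect_equal(sum(Wr[tr]), sum(edges$w[best]), tolerance = 1e-12)
  }
})

test_that("an excluded-edge tree request fails gracefully when disconnected", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.5
  # excluding the only edge to node 3 leaves no spanning tree
  expect_null(maximum_spanning_tree(W, excluded_edges = cbind(1, 3)))
})

test_that("omst returns the only candidate when the input is a tree", {
  W <- matrix(0, 5, 5)
  for (k in 1:4) W[k, k + 1] <- W[k + 1, k] <- runif(1, 0.3, 0.9)
  res <- omst_select(W)
  expect_equal(res$m_star, 1L)
  expect_equal(sum(res$graph), 2 * 4)  # 4 edges, symmetric storage
  expect_equal(nrow(res$diagnostics), 1L)
})

test_that("omst matches the exhaustive GCE oracle on random small graphs", {
  set.seed(66)
  for (rep in 1:100) {
    n <- sample(4:6, 1)
    W <- random_weighted_graph(n)
    res <- omst_select(W)
    ora <- oracle_omst(W)
    expect_equal(res$m_star, ora$m_star)
    key <- function(E) sort(paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2])))
    expect_equal(key(res$edges), key(ora$edges))
    expect_equal(res$diagnostics$gce, ora$gce, tolerance = 1e-10)
  }
})

test_that("omst output is connected, trees are edge-disjoint, cost increases", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    W <- random_weighted_graph(n, p = 0.6)
    res <- omst_select(W)
    d <- res$diagnostics
    # connected and spanning (contains the round-1 tree)
    expect_true(all(is.finite(oracle_floyd_warshall(unclass(res$graph)))))
    # edge-disjoint rounds: selected edge count is exactly rounds * (n-1)
    expect_equal(d$n_edges, d$round * (n - 1))
    expect_false(any(duplicated(paste(res$edges[, 1], res$edges[, 2]))))
    # cost strictly increasing, weighted GE non-decreasing, GCE finite
    expect_true(all(diff(d$cost) > 0))
    expect_true(all(diff(d$ge_w) > -1e-12))
    expect_true(all(is.finite(d$gce)))
  }
})

test_that("disconnected inputs are rejected at round 1", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.8
  expect_error(omst_select(W), "disconnected")
})

test_that("binarize builds symmetric 0/1 adjacency from edge sets", {
  nodes <- letters[1:5]
  empty <- binarize(matrix(numeric(0), 0, 2), nodes)
  expect_equal(sum(empty), 0)
  tree <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  A <- binarize(tree, nodes)
  expect_equal(sum(A), 8)  # 2 * (N - 1) nonzero entries
  expect_identical(unclass(A), t(unclass(A)))
  # idempotent under re-extraction of its own edges
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  expect_identical(unclass(binarize(idx, nodes)), unclass(A))
  expect_error(binarize(cbind(1, 9), nodes), "unknown node")
  expect_error(binarize(cbind(2, 2), nodes), "self-loops")
})
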