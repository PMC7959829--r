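# Independent oracles used to validate the implementation. These are kept
# deliberately naive (enumeration, dynamic programming) and share no code
# with the package internals.

# All-pairs shortest paths by Floyd-Warshall dynamic programming.
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eff <- function(A) {
  n <- nrow(A)
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1L))
}

# Weighted global efficiency by Floyd-Warshall on transformed distances.
oracle_weighted_ge <- function(W, distance = "inverse") {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  pos <- W > 0
  D[pos] <- if (distance == "inverse") 1 / W[pos] else 1 - W[pos]
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Is the graph on `n` nodes formed by `edges` (2-column index matrix)
# connected and spanning? Checked by reachability closure.
oracle_connected <- function(edges, n) {
  reach <- rep(FALSE, n)
  reach[1L] <- TRUE
  repeat {
    new <- reach
    for (r in seq_len(nrow(edges))) {
      if (reach[edges[r, 1L]] || reach[edges[r, 2L]]) {
        new[edges[r, 1L]] <- TRUE
        new[edges[r, 2L]] <- TRUE
      }
    }
    if (identical(new, reach)) break
    reach <- new
  }
  all(reach)
}

# Maximum-weight spanning tree by exhaustive enumeration of all N-1 edge
# subsets of the available edges. Returns row indices into `edges`
# (data.frame i, j, w), or NULL if none spans.
oracle_max_spanning_tree <- function(edges, n, available) {
  if (length(available) < n - 1L) return(NULL)
  combos <- utils::combn(available, n - 1L)
  best <- NULL
  best_w <- -Inf
  for (c_idx in seq_len(ncol(combos))) {
    rows <- combos[, c_idx]
    em <- cbind(edges$i[rows], edges$j[rows])
    if (!oracle_connected(em, n)) next
    w <- sum(edges$w[rows])
    if (w > best_w) {
      best_w <- w
      best <- rows
    }
  }
  best
}

# Full OMST by exhaustive per-round tree enumeration and GCE evaluation.
oracle_omst <- function(W, distance = "inverse") {
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], w = W[idx])
  total_w <- sum(edges$w)
  available <- seq_len(nrow(edges))
  selected <- integer(0)
  rounds <- list()
  gce <- numeric(0)
  repeat {
    tree <- oracle_max_spanning_tree(edges, n, available)
    if (is.null(tree)) break
    selected <- c(selected, tree)
    available <- setdiff(available, tree)
    Wsel <- matrix(0, n, n)
    for (r in selected) {
      Wsel[edges$i[r], edges$j[r]] <- edges$w[r]
      Wsel[edges$j[r], edges$i[r]] <- edges$w[r]
    }
    rounds[[length(rounds) + 1L]] <- selected
    gce <- c(gce, oracle_weighted_ge(Wsel, distance) -
               sum(edges$w[selected]) / total_w)
    if (length(rounds) >= n - 1L) break
  }
  m_star <- which.max(gce)
  rows <- rounds[[m_star]]
  list(m_star = m_star, gce = gce,
       edges = cbind(i = edges$i[rows], j = edges$j[rows]))
}

# Benjamini-Hochberg by the step-up definition: q_(i) = min_{j >= i}
# min(1, p_(j) * m / j) on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Random symmetric 0/1 adjacency.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  A + t(A)
}

# Random connected binary graph (rejection sampling).
random_connected_adjacency <- function(n, p = 0.5) {
  repeat {
    A <- random_adjacency(n, p)
    if (all(is.finite(oracle_floyd_warshall(A)))) return(A)
  }
}

# Random weighted graph with distinct positive weights, connected.
random_weighted_graph <- function(n, p = 0.7) {
  repeat {
    A <- random_adjacency(n, p)
    if (!all(is.finite(oracle_floyd_warshall(A)))) next
    W <- matrix(0, n, n)
    m <- sum(upper.tri(A) & A > 0)
    W[upper.tri(W) & A > 0] <- stats::runif(m, 0.05, 1)
    return(W + t(W))
  }
}

# Adjacency from a graph index (bitmask over the upper triangle), for
# exhaustive enumeration of all labeled graphs on n nodes.
adjacency_from_bits <- function(bits, n) {
  m <- n * (n - 1L) / 2L
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(intToBits(bits))[seq_len(m)]
  A + t(A)
}
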