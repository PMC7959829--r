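# Orthogonal minimal spanning tree (OMST) filtering: iteratively extract
# edge-disjoint maximum spanning trees and keep the union of rounds that
# maximizes global-cost-efficiency, yielding a connected binary graph of
# the strongest connections without picking an arbitrary density threshold.

#' Absolute-value connection weights
#'
#' Negative similarities (inhibition-like connections) carry topological
#' information, so the filtering stage operates on connection magnitude:
#' `w(i,j) = |s(i,j)|`, with the diagonal dropped.
#'
#' @param S A `similarity_matrix` (or symmetric numeric matrix).
#' @return Object of class `weighted_graph`: list with `labels` and the
#'   symmetric non-negative `weights` matrix (zero diagonal).
#' @export
absolutize <- function(S) {
  M <- unclass(S)
  assert_square_symmetric(M, "S")
  W <- abs(M)
  diag(W) <- 0
  labels <- rownames(M) %||% as.character(seq_len(nrow(M)))
  structure(list(labels = labels, weights = W), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted graph: %d nodes, %d positive-weight edges\n",
              length(x$labels), pos))
  invisible(x)
}

as_weighted_graph <- function(g) {
  if (inherits(g, "weighted_graph")) return(g)
  if (is.matrix(g)) return(absolutize(g))
  stop("'g' must be a weighted_graph or symmetric matrix", call. = FALSE)
}

# Kruskal maximum spanning tree over the positive-weight edges of `edges`
# (data.frame i, j, w), skipping rows flagged in `excluded`. Deterministic:
# edges are taken in (descending weight, ascending (i, j)) order. Returns
# integer row indices of the tree edges, or NULL if the non-excluded graph
# does not span all `n` nodes.
kruskal_mst <- function(edges, n, excluded = rep(FALSE, nrow(edges))) {
  ord <- order(-edges$w, edges$i, edges$j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  chosen <- integer(0)
  for (k in ord) {
    if (excluded[k] || edges$w[k] <= 0) next
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      chosen <- c(chosen, k)
      if (length(chosen) == n - 1L) break
    }
  }
  if (length(chosen) < n - 1L) return(NULL)
  chosen
}

#' Maximum spanning tree of a weighted graph
#'
#' Deterministic Kruskal construction over positive-weight edges: edges are
#' considered in descending weight order, ties broken by ascending `(i, j)`
#' node-index order, so equal-weight graphs always yield the
#' lexicographically smallest tree.
#'
#' @param g A `weighted_graph` or symmetric matrix.
#' @param excluded_edges Optional 2-column matrix of node-index pairs to
#'   ignore (already-used edges in the OMST iteration).
#' @return A `(N-1) x 2` integer matrix of node-index pairs (`i < j`) with
#'   a `labels` attribute, or `NULL` if the remaining graph is
#'   disconnected (no further spanning tree exists).
#' @export
maximum_spanning_tree <- function(g, excluded_edges = NULL) {
  g <- as_weighted_graph(g)
  n <- length(g$labels)
  edges <- edge_list(g$weights)
  excluded <- rep(FALSE, nrow(edges))
  if (!is.null(excluded_edges) && nrow(excluded_edges)) {
    key <- paste(pmin(excluded_edges[, 1L], excluded_edges[, 2L]),
                 pmax(excluded_edges[, 1L], excluded_edges[, 2L]))
    excluded <- paste(edges$i, edges$j) %in% key
  }
  idx <- kruskal_mst(edges, n, excluded)
  if (is.null(idx)) return(NULL)
  out <- cbind(i = edges$i[idx], j = edges$j[idx])
  attr(out, "labels") <- g$labels
  out
}

# Weighted global efficiency of the graph formed by `edges` (rows of the
# full edge table) on n nodes, with edge distance d = 1/w or 1 - w.
weighted_global_efficiency <- function(edges, rows, n, distance = "inverse") {
  if (!length(rows)) return(0)
  w <- edges$w[rows]
  d <- if (distance == "inverse") 1 / w else 1 - w
  d[d <= 0] <- .Machine$double.eps  # w = 1 under "one-minus": zero distance
  ig <- igraph::make_graph(rbind(edges$i[rows], edges$j[rows]), n = n,
                           directed = FALSE)
  D <- igraph::distances(ig, weights = d)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' OMST selection of the strongest connections
#'
#' Round `m` adds the maximum spanning tree that is edge-disjoint from all
#' previous rounds ("orthogonal"). After each round, global-cost-efficiency
#' is evaluated on the union: `GCE(m) = GE_w(union) - Cost(m)`, where
#' `Cost(m)` is the selected weight mass as a fraction of total weight and
#' `GE_w` is weighted global efficiency with edge distance `1/w` (or
#' `1 - w`). Iteration stops when no further disjoint spanning tree exists
#' or `max_rounds` is reached; the returned graph is the union at the round
#' maximizing GCE, binarized. It always contains the round-1 tree, hence is
#' connected and spans all nodes.
#'
#' @param g A `weighted_graph` (see [absolutize()]) or symmetric matrix.
#' @param distance Distance transform inside the GCE criterion:
#'   `"inverse"` (`1/w`, default) or `"one-minus"` (`1 - w`).
#' @param max_rounds Cap on rounds (default `N - 1`).
#' @return Object of class `omst_result`: list with `graph` (a
#'   [binarize()] `binary_graph`), `m_star` (chosen round), `edges`
#'   (selected node-index pairs) and `diagnostics` (data.frame with one row
#'   per completed round: `round`, `n_edges`, `cost`, `ge_w`, `gce`).
#' @export
omst_select <- function(g, distance = c("inverse", "one-minus"), max_rounds = NULL) {
  g <- as_weighted_graph(g)
  distance <- match.arg(distance)
  n <- length(g$labels)
  edges <- edge_list(g$weights)
  max_rounds <- max_rounds %||% (n - 1L)
  total_w <- sum(edges$w[edges$w > 0])

  excluded <- rep(FALSE, nrow(edges))
  round_edges <- list()
  diag_rows <- list()
  selected <- integer(0)
  for (m in seq_len(max_rounds)) {
    tree <- kruskal_mst(edges, n, excluded)
    if (is.null(tree)) {
      if (m == 1L) stop("graph is disconnected on positive-weight edges; no spanning tree exists",
                        call. = FALSE)
      break
    }
    excluded[tree] <- TRUE
    selected <- c(selected, tree)
    round_edges[[m]] <- selected
    diag_rows[[m]] <- data.frame(
      round = m, n_edges = length(selected),
      cost = sum(edges$w[selected]) / total_w,
      ge_w = weighted_global_efficiency(edges, selected, n, distance))
  }
  diagnostics <- do.call(rbind, diag_rows)
  diagnostics$gce <- diagnostics$ge_w - diagnostics$cost
  m_star <- which.max(diagnostics$gce)
  sel <- round_edges[[m_star]]
  edge_mat <- cbind(i = edges$i[sel], j = edges$j[sel])
  structure(list(graph = binarize(edge_mat, g$labels),
                 m_star = m_star, edges = edge_mat,
                 diagnostics = diagnostics),
            class = "omst_result")
}

#' @export
print.omst_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("OMST filtering: %d round(s) completed, m* = %d\n", nrow(d), x$m_star))
  cat(sprintf("  selected %d edges on %d nodes (cost %.3f, GCE %.4f)\n",
              nrow(x$edges), nrow(x$graph), d$cost[x$m_star], d$gce[x$m_star]))
  invisible(x)
}

#' Binary adjacency from an edge set
#'
#' @param edges 2-column matrix of node indices (or labels matching
#'   `nodes`); may have zero rows.
#' @param nodes Character vector of node labels defining matrix order.
#' @return Object of class `binary_graph`: symmetric 0/1 integer matrix
#'   with zero diagonal and `nodes` as dimnames.
#' @export
binarize <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges)) {
    ei <- edges[, 1L]; ej <- edges[, 2L]
    if (is.character(ei)) {
      ei <- match(ei, nodes); ej <- match(ej, nodes)
    }
    if (anyNA(ei) || anyNA(ej) || any(ei < 1 | ei > n | ej < 1 | ej > n)) {
      stop("edge references unknown node", call. = FALSE)
    }
    if (any(ei == ej)) stop("self-loops are not allowed", call. = FALSE)
    A[cbind(ei, ej)] <- 1L
    A[cbind(ej, ei)] <- 1L
  }
  structure(A, class = c("binary_graph", "matrix"))
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges\n",
              nrow(x), sum(x[upper.tri(x)])))
  invisible(x)
}
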