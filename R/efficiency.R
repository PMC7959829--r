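# Binary-graph efficiency: global (whole-network parallel information
# transfer), nodal (a node's importance for transfer) and local (how well
# a node's neighborhood exchanges information without it). All metrics use
# inverse shortest path lengths, with 1/Inf := 0 for unreachable pairs.

as_adjacency <- function(g) {
  A <- unclass(g)
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("'g' must be a square adjacency matrix or binary_graph", call. = FALSE)
  }
  if (any(A != 0 & A != 1)) stop("adjacency must be 0/1", call. = FALSE)
  if (any(diag(A) != 0)) stop("self-loops are not allowed", call. = FALSE)
  if (any(A != t(A))) stop("adjacency must be symmetric (undirected graph)", call. = FALSE)
  A
}

#' Shortest path lengths of a binary graph
#'
#' Hop-count distances computed by breadth-first traversal from every
#' source node; unreachable pairs are `Inf`.
#'
#' @param g A `binary_graph` or symmetric 0/1 adjacency matrix.
#' @return Symmetric numeric matrix `L` with `L[i, i] = 0`.
#' @export
shortest_path_lengths <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  L <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    frontier <- src
    d <- 0
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      d <- d + 1
      dist[nxt] <- d
      frontier <- nxt
    }
    L[src, ] <- dist
  }
  L
}

inverse_distance_matrix <- function(g) {
  L <- shortest_path_lengths(g)
  inv <- 1 / L
  diag(inv) <- 0
  inv
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all ordered node pairs:
#' `E_glob(G) = 1/(N(N-1)) * sum_{i != j} 1/L_ij`, with `1/Inf := 0`.
#' Equals 1 for a complete graph and 0 for an edgeless one.
#'
#' @param g A `binary_graph` or symmetric 0/1 adjacency matrix with
#'   `N >= 2` nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  inv <- inverse_distance_matrix(g)
  n <- nrow(inv)
  if (n < 2L) stop("global efficiency requires at least 2 nodes", call. = FALSE)
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' For each node `i`, the mean inverse shortest path length to every other
#' node: `E_nodal(i) = 1/(N-1) * sum_{j != i} 1/L_ij`. The mean of nodal
#' efficiencies over nodes equals the global efficiency.
#'
#' @inheritParams global_efficiency
#' @return Named numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(g) {
  inv <- inverse_distance_matrix(g)
  n <- nrow(inv)
  if (n < 2L) stop("nodal efficiency requires at least 2 nodes", call. = FALSE)
  rowSums(inv) / (n - 1)
}

#' Local efficiency
#'
#' For each node `i`, the global efficiency of the subgraph induced on
#' `i`'s direct neighbors (excluding `i` itself): `E_local(i) =
#' E_glob(G_i)`. Nodes with fewer than 2 neighbors get 0 (the global
#' efficiency of their neighborhood is undefined; 0 is the standard
#' convention).
#'
#' @inheritParams global_efficiency
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- as_adjacency(g)
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    out[i] <- if (length(nb) < 2L) 0 else global_efficiency(A[nb, nb, drop = FALSE])
  }
  names(out) <- rownames(A)
  out
}

#' Efficiency profile of one subject's network
#'
#' Bundles global, nodal and local efficiency of a binary graph.
#'
#' @inheritParams global_efficiency
#' @param subject_id,measure Optional tags carried into the output.
#' @return Object of class `efficiency_profile`: list with `e_glob`,
#'   `e_nodal`, `e_local`, `labels`, `subject_id`, `measure`.
#' @export
efficiency_profile <- function(g, subject_id = NA_character_, measure = NA_character_) {
  A <- as_adjacency(g)
  structure(list(
    e_glob  = global_efficiency(A),
    e_nodal = nodal_efficiency(A),
    e_local = local_efficiency(A),
    labels  = rownames(A) %||% as.character(seq_len(nrow(A))),
    subject_id = subject_id, measure = measure
  ), class = "efficiency_profile")
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat(sprintf("Efficiency profile (subject '%s', measure '%s', %d nodes)\n",
              x$subject_id, x$measure, length(x$labels)))
  cat(sprintf("  global %.4f; nodal [%.4f, %.4f]; local [%.4f, %.4f]\n",
              x$e_glob, min(x$e_nodal), max(x$e_nodal),
              min(x$e_local), max(x$e_local)))
  invisible(x)
}

#' @export
as.data.frame.efficiency_profile <- function(x, ...) {
  rbind(
    data.frame(subject_id = x$subject_id, measure = x$measure,
               metric = "global", parcel = "ALL", value = x$e_glob,
               stringsAsFactors = FALSE),
    data.frame(subject_id = x$subject_id, measure = x$measure,
               metric = "nodal", parcel = x$labels, value = unname(x$e_nodal),
               stringsAsFactors = FALSE),
    data.frame(subject_id = x$subject_id, measure = x$measure,
               metric = "local", parcel = x$labels, value = unname(x$e_local),
               stringsAsFactors = FALSE)
  )
}
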