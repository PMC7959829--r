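# Morphological distribution similarity: for each pair of parcels, the
# Pearson correlation of their vertex-value frequency histograms computed
# over shared bins spanning the pooled value range.

#' Shared histogram bin edges for a parcel pair
#'
#' Edges span the pooled range of both parcels' values, divided into
#' `n_bins` bins of equal width. Bins are left-closed/right-open except the
#' last bin, which is closed, so every pooled value falls in exactly one
#' bin. A shared axis is what makes the two frequency vectors comparable.
#'
#' @param values_a,values_b Numeric vectors of vertex values (non-empty).
#' @param n_bins Number of bins (default 30).
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
pooled_bin_edges <- function(values_a, values_b, n_bins = 30L) {
  stopifnot_scalar_count(n_bins, "n_bins", min = 2L)
  if (!length(values_a) || !length(values_b)) {
    stop("both value multisets must be non-empty", call. = FALSE)
  }
  pooled <- range(c(values_a, values_b))
  if (pooled[1L] == pooled[2L]) {
    cond <- structure(
      class = c("morphnet_degenerate_range", "error", "condition"),
      list(message = sprintf("degenerate pooled range: all values equal %g", pooled[1L]),
           call = sys.call(-1L)))
    stop(cond)
  }
  seq(pooled[1L], pooled[2L], length.out = n_bins + 1L)
}

#' Frequency histograms of a parcel pair over shared edges
#'
#' Counts how many vertices of each parcel fall into each bin. Values must
#' lie within `[edges[1], edges[length(edges)]]`; a value equal to the last
#' edge is counted in the final (closed) bin.
#'
#' @param values_a,values_b Numeric vectors.
#' @param edges Bin edges from [pooled_bin_edges()] over the same pooled
#'   values.
#' @return Object of class `pair_histogram`: list with `bin_edges`,
#'   `freq_a`, `freq_b` (integer counts of length `length(edges) - 1`).
#' @export
pair_frequencies <- function(values_a, values_b, edges) {
  n_bins <- length(edges) - 1L
  if (n_bins < 1L || is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be strictly increasing with at least 2 values", call. = FALSE)
  }
  count_one <- function(v, which) {
    if (any(v < edges[1L] | v > edges[n_bins + 1L])) {
      stop(sprintf("values_%s outside histogram range [%g, %g]",
                   which, edges[1L], edges[n_bins + 1L]), call. = FALSE)
    }
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = n_bins)
  }
  structure(list(bin_edges = edges,
                 freq_a = count_one(values_a, "a"),
                 freq_b = count_one(values_b, "b")),
            class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf("Pair histogram: %d bins over [%g, %g]; n_a = %d, n_b = %d\n",
              length(x$freq_a), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
              sum(x$freq_a), sum(x$freq_b)))
  invisible(x)
}

#' Distribution similarity of two parcels
#'
#' Pearson correlation of the two vertex-frequency vectors over shared
#' pooled-range bins. Degenerate cases — a pooled range of zero width, or a
#' frequency vector with no variance across bins — yield a similarity of 0
#' with a warning, keeping the similarity matrix complete (0 is neutral
#' after absolutization and OMST filtering).
#'
#' @inheritParams pooled_bin_edges
#' @return Similarity in `[-1, 1]`.
#' @export
distribution_similarity <- function(values_a, values_b, n_bins = 30L) {
  edges <- tryCatch(pooled_bin_edges(values_a, values_b, n_bins),
                    morphnet_degenerate_range = function(e) NULL)
  degenerate_zero <- function(msg) {
    warning(warningCondition(msg, class = "morphnet_degenerate_similarity"))
    0
  }
  if (is.null(edges)) {
    return(degenerate_zero("degenerate pooled range; similarity set to 0"))
  }
  h <- pair_frequencies(values_a, values_b, edges)
  if (stats::sd(h$freq_a) == 0 || stats::sd(h$freq_b) == 0) {
    return(degenerate_zero("zero-variance frequency vector; similarity set to 0"))
  }
  stats::cor(h$freq_a, h$freq_b)
}

#' Per-subject morphological similarity matrix
#'
#' Applies [distribution_similarity()] to every pair of retained parcels
#' for one measure, giving a P-by-P symmetric matrix with unit diagonal —
#' the subject's morphological network for that measure. Row/column order
#' is the parcel order of the input.
#'
#' @param sm A `subject_morphometry` with at least 3 parcels.
#' @param measure One of `"volume"`, `"area"`, `"thickness"`.
#' @param n_bins Number of histogram bins (default 30).
#' @return Object of class `similarity_matrix`: numeric matrix with
#'   attributes `subject_id`, `measure`, `n_bins` and `n_degenerate` (count
#'   of pairs that fell back to similarity 0).
#' @export
build_similarity_matrix <- function(sm, measure = c("volume", "area", "thickness"),
                                    n_bins = 30L) {
  measure <- match.arg(measure)
  if (!inherits(sm, "subject_morphometry")) {
    stop("'sm' must be a subject_morphometry", call. = FALSE)
  }
  labels <- names(sm$parcels)
  P <- length(labels)
  if (P < 3L) stop("need at least 3 parcels to build a network", call. = FALSE)
  values <- lapply(sm$parcels, `[[`, measure)
  S <- diag(1, P)
  n_degenerate <- 0L
  for (i in seq_len(P - 1L)) {
    for (j in seq.int(i + 1L, P)) {
      s <- withCallingHandlers(
        tryCatch(distribution_similarity(values[[i]], values[[j]], n_bins),
                 error = function(e) {
                   stop(sprintf("parcel pair (%s, %s): %s",
                                labels[i], labels[j], conditionMessage(e)),
                        call. = FALSE)
                 }),
        morphnet_degenerate_similarity = function(w) {
          n_degenerate <<- n_degenerate + 1L
          invokeRestart("muffleWarning")
        })
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  dimnames(S) <- list(labels, labels)
  if (n_degenerate > 0L) {
    warning(sprintf("subject '%s' (%s): %d degenerate parcel pair(s) set to similarity 0",
                    sm$subject_id, measure, n_degenerate), call. = FALSE)
  }
  structure(S, class = c("similarity_matrix", "matrix"),
            subject_id = sm$subject_id, measure = measure,
            n_bins = as.integer(n_bins), n_degenerate = n_degenerate)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("Similarity matrix: subject '%s', measure '%s', %d parcels, %d bins\n",
              attr(x, "subject_id"), attr(x, "measure"), nrow(x), attr(x, "n_bins")))
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f; degenerate pairs: %d\n",
              min(off), max(off), mean(off), attr(x, "n_degenerate")))
  invisible(x)
}

#' @export
plot.similarity_matrix <- function(x, ...) {
  P <- nrow(x)
  graphics::image(seq_len(P), seq_len(P), t(unclass(x))[, P:1, drop = FALSE],
                  zlim = c(-1, 1), col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "parcel", ylab = "parcel",
                  main = sprintf("%s similarity (%s)", attr(x, "measure"),
                                 attr(x, "subject_id")), ...)
  invisible(x)
}

#' Write / read a labeled similarity matrix as TSV
#'
#' @param S A `similarity_matrix` (or plain labeled matrix).
#' @param path Output path.
#' @return `path` invisibly; `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(S, path) {
  df <- data.frame(parcel = rownames(S), as.data.frame(unclass(S), check.names = FALSE),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  M
}
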