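# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score a numeric vector; errors on zero variance (degenerate predictor).
zscore <- function(x, label = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("column '%s' has zero variance; cannot standardize", label),
         call. = FALSE)
  }
  (x - mean(x)) / s
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Upper-triangle edge list of a symmetric weight matrix (positive weights).
edge_list <- function(W) {
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L], w = W[idx])
}

assert_square_symmetric <- function(M, name = "matrix", tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(M - t(M))) > tol) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic per-stream seed derived from a base seed; stays < 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) %% 2011L
}
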