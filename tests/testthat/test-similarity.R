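test_that("pooled bin edges span the union range in equal widths", {
  e <- pooled_bin_edges(c(0, 12, 30), c(4, 25), n_bins = 30L)
  expect_equal(e, 0:30)
  # the worked example: range 5.4-66.4 over 30 bins -> width 2.03
  e2 <- pooled_bin_edges(c(5.4, 20), c(15, 66.4), n_bins = 30L)
  expect_equal(length(e2), 31L)
  width <- unique(round(diff(e2), 10))
  expect_length(width, 1L)
  expect_equal(round(width, 2), 2.03)
  # degenerate pooled range signals a classed condition
  expect_error(pooled_bin_edges(7, 7), class = "morphnet_degenerate_range")
})

test_that("pair frequencies count every value into exactly one bin", {
  h <- pair_frequencies(c(0.5, 1.5, 1.6), c(0.2, 1.9), edges = c(0, 1, 2))
  expect_equal(h$freq_a, c(1L, 2L))
  expect_equal(h$freq_b, c(1L, 1L))
  # a value equal to the last edge falls in the final (closed) bin
  h2 <- pair_frequencies(c(0, 2), c(1), edges = c(0, 1, 2))
  expect_equal(h2$freq_a, c(1L, 1L))
  # out-of-range values are an internal consistency error
  expect_error(pair_frequencies(c(0.5, 2.5), 1, edges = c(0, 1, 2)),
               "outside histogram range")
})

test_that("bin counts conserve multiset sizes (vs per-value assignment oracle)", {
  set.seed(101)
  for (rep in 1:25) {
    a <- rlnorm(sample(5:80, 1), 3, 0.4)
    b <- rlnorm(sample(5:80, 1), 3.2, 0.5)
    nb <- sample(2:30, 1)
    edges <- pooled_bin_edges(a, b, nb)
    h <- pair_frequencies(a, b, edges)
    expect_equal(sum(h$freq_a), length(a))
    expect_equal(sum(h$freq_b), length(b))
    # brute-force per-value bin assignment
    assign_one <- function(x) {
      for (k in seq_len(nb)) {
        hi <- edges[k + 1L]
        if (x >= edges[k] && (x < hi || (k == nb && x <= hi))) return(k)
      }
      stop("unassigned")
    }
    expect_equal(h$freq_a, tabulate(vapply(a, assign_one, 1L), nb))
    expect_equal(h$freq_b, tabulate(vapply(b, assign_one, 1L), nb))
  }
})

test_that("distribution similarity matches the hand-evaluated Pearson value", {
  # freq_a = (3,1,0,0), freq_b = (0,0,1,3) over 4 unit bins -> r = -2/3
  a <- c(0.5, 0.6, 0.7, 1.5)
  b <- c(2.5, 3.2, 3.5, 4.0)
  expect_equal(distribution_similarity(a, b, n_bins = 4L), -2 / 3,
               tolerance = 1e-12)
  # identical multisets are perfectly similar regardless of bin count
  x <- rlnorm(40, 3, 0.5)
  for (nb in c(5L, 30L, 60L)) {
    expect_equal(distribution_similarity(x, x, nb), 1)
  }
})

test_that("degenerate pairs map to similarity 0 with a classed warning", {
  expect_warning(s <- distribution_similarity(c(7, 7), c(7, 7, 7)),
                 class = "morphnet_degenerate_similarity")
  expect_equal(s, 0)
  # all mass in every bin equal -> zero-variance frequency vector
  expect_warning(s2 <- distribution_similarity(c(0.5, 1.5), c(0.2, 0.8), n_bins = 2L),
                 class = "morphnet_degenerate_similarity")
  expect_equal(s2, 0)
})

test_that("similarity is symmetric, proportion-invariant and jointly scale-invariant", {
  set.seed(202)
  for (rep in 1:200) {
    a <- rlnorm(sample(10:60, 1), 3, 0.4)
    b <- rlnorm(sample(10:60, 1), 3 + runif(1, -0.5, 0.5), 0.5)
    s <- distribution_similarity(a, b)
    # symmetry in the arguments
    expect_equal(distribution_similarity(b, a), s, tolerance = 1e-12)
    # Pearson on proportions equals Pearson on raw counts
    h <- pair_frequencies(a, b, pooled_bin_edges(a, b))
    expect_equal(cor(h$freq_a / length(a), h$freq_b / length(b)), s,
                 tolerance = 1e-12)
    # doubling every value in BOTH parcels leaves the similarity unchanged
    expect_equal(distribution_similarity(2 * a, 2 * b), s, tolerance = 1e-9)
  }
})

test_that("the similarity matrix is the composition of pairwise calls", {
  sm <- toy_subject(list(`A(lh)` = rlnorm(60, 3, 0.3),
                         `B(lh)` = rlnorm(70, 3.1, 0.4),
                         `C(lh)` = rlnorm(80, 3.4, 0.5)))
  S <- build_similarity_matrix(sm, "volume")
  vols <- lapply(sm$parcels, `[[`, "volume")
  expect_equal(S["A(lh)", "B(lh)"],
               distribution_similarity(vols[[1]], vols[[2]]))
  expect_equal(S["A(lh)", "C(lh)"],
               distribution_similarity(vols[[1]], vols[[3]]))
  expect_equal(S["B(lh)", "C(lh)"],
               distribution_similarity(vols[[2]], vols[[3]]))
  expect_equal(diag(unclass(S)), setNames(rep(1, 3), rownames(S)))
  # exact (bit-equal) symmetry
  expect_identical(unclass(S), t(unclass(S)))
  expect_true(all(S >= -1 & S <= 1))
})

test_that("permuting parcel order permutes the matrix consistently", {
  set.seed(33)
  vols <- list(`A(lh)` = rlnorm(50, 3, 0.3), `B(lh)` = rlnorm(60, 3.2, 0.4),
               `C(lh)` = rlnorm(70, 3.4, 0.5), `D(lh)` = rlnorm(55, 2.9, 0.35))
  sm1 <- toy_subject(vols)
  perm <- c(3, 1, 4, 2)
  sm2 <- toy_subject(vols[perm])
  S1 <- strip_attrs(build_similarity_matrix(sm1, "volume"))
  S2 <- strip_attrs(build_similarity_matrix(sm2, "volume"))
  expect_equal(S2, S1[perm, perm])
})

test_that("parcels sharing a distribution are the most similar pair", {
  set.seed(44)
  shared <- function() rlnorm(80, 3, 0.35)
  wins <- 0L
  for (rep in 1:20) {
    sm <- toy_subject(list(`P(lh)` = shared(), `P(rh)` = shared(),
                           far = rlnorm(80, 4.5, 0.2)))
    S <- build_similarity_matrix(sm, "volume")
    wins <- wins + (S["P(lh)", "P(rh)"] > S["P(lh)", "far"] &&
                      S["P(lh)", "P(rh)"] > S["P(rh)", "far"])
  }
  expect_gte(wins, 18L)
})

test_that("similarity matrices survive a TSV round trip", {
  sm <- toy_subject(list(`A(lh)` = rlnorm(50, 3, 0.3), `B(lh)` = rlnorm(60, 3.2, 0.4),
                         `C(lh)` = rlnorm(70, 3.4, 0.5)))
  S <- build_similarity_matrix(sm, "volume")
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(S, path)
  back <- read_matrix_tsv(path)
  expect_equal(rownames(back), rownames(S))
  expect_equal(unname(back), unname(strip_attrs(S)), tolerance = 1e-12)
})
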