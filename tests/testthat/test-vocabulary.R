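test_that("full vocabularies have exactly the closed-form dimension", {
  for (t in c(2L, 4L, 6L, 8L)) {
    alpha <- c(six_alpha, "X", "Z")[seq_len(t)]
    for (k in 1:5) for (g in 0:k) {
      v <- build_vocabulary(mode = "full", alphabet = alpha, k = k, g = g)
      expect_length(v$patterns, full_dimension(t, k, g))
      expect_false(anyDuplicated(v$patterns) > 0)
    }
  }
})

test_that("observed vocabulary is the sorted union of table patterns", {
  tab <- count_gapped(as_reduced_seq("LBBBWWG"), 3, 1)
  v <- build_vocabulary(list(tab), "observed")
  expect_length(v$patterns, 12L)
  expect_identical(v$patterns, sort(v$patterns, method = "radix"))
  # gap symbol sorts after the class letters
  expect_identical(v$patterns[length(v$patterns)], "_WW")
  empty <- build_vocabulary(list(), "observed", k = 3, g = 1)
  expect_length(empty$patterns, 0L)
})

test_that("observed vocabulary is bounded by (and can reach) the full dimension", {
  set.seed(19)
  for (i in 1:10) {
    r <- random_reduced_seq(sample(10:100, 1), c("B", "W"))
    tab <- count_gapped(r, 3, 1)
    obs <- build_vocabulary(list(tab), "observed", alphabet = c("B", "W"))
    expect_lte(length(obs$patterns), full_dimension(2, 3, 1))
  }
  # de-Bruijn-style string containing every binary 3-mer
  db <- as_reduced_seq("BBBWWWBWBB")
  saturated <- build_vocabulary(list(count_gapped(db, 3, 1)), "observed",
                                alphabet = c("B", "W"))
  expect_length(saturated$patterns, full_dimension(2, 3, 1))
})

test_that("mixed k or g across tables is rejected", {
  t1 <- count_gapped(as_reduced_seq("LBBBWWG"), 3, 1)
  t2 <- count_gapped(as_reduced_seq("LBBBWWG"), 3, 2)
  expect_error(build_vocabulary(list(t1, t2), "observed"), "same k and g")
})

test_that("vectorize projects counts onto the vocabulary with zero fill", {
  tab <- structure(list(counts = c(B_B = 2L, B_W = 3L, W_B = 2L),
                        k = 3L, g = 1L, window_total = 21L),
                   class = "gkm_counts")
  vocab <- build_vocabulary(list(), "observed", k = 3, g = 1)
  vocab$patterns <- c("B_B", "B_W", "W_B", "W_W")
  v <- vectorize(tab, vocab)
  expect_identical(unname(v), c(2, 3, 2, 0))
  freq <- vectorize(tab, vocab, "frequency")
  expect_equal(unname(freq), c(2, 3, 2, 0) / 21)
  empty <- structure(list(counts = integer(0), k = 3L, g = 1L,
                          window_total = 0L), class = "gkm_counts")
  expect_identical(unname(vectorize(empty, vocab)), c(0, 0, 0, 0))
})

test_that("frequency vectors sum to one when the vocabulary covers the table", {
  set.seed(3)
  for (i in 1:8) {
    r <- random_reduced_seq(sample(10:60, 1))
    tab <- count_gapped(r, 3, 1)
    vocab <- build_vocabulary(list(tab), "observed")
    expect_equal(sum(vectorize(tab, vocab, "frequency")), 1)
  }
})

test_that("gkm_feature_matrix stacks aligned rows and reuses vocabularies", {
  seqs <- c(a = "RIAVYYPG", b = "PPGGCCRR", c = "LLLIVAMF")
  fm <- gkm_feature_matrix(seqs, k = 3, g = 1)
  expect_identical(rownames(fm$matrix), c("a", "b", "c"))
  expect_identical(colnames(fm$matrix), fm$vocab$patterns)
  # projecting new sequences onto a training vocabulary keeps the columns
  fm2 <- gkm_feature_matrix(c(d = "GGGGGGGG"), k = 3, g = 1, vocab = fm$vocab)
  expect_identical(colnames(fm2$matrix), colnames(fm$matrix))
  # dimension-reduction report is consistent
  dr <- dimension_reduction(fm$vocab)
  expect_identical(dr$full, 108L)
  expect_equal(dr$reduction_pct, 100 * (1 - dr$observed / 108))
})
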