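test_that("3-mer counting of the worked-example sequence finds 5 types", {
  tab <- count_kmers(as_reduced_seq("LBBBWWG"), 3)
  expect_length(tab$counts, 5L)
  expect_identical(sort(names(tab$counts)),
                   sort(c("LBB", "BBB", "BBW", "BWW", "WWG")))
  expect_true(all(tab$counts == 1L))
  expect_identical(tab$window_total, 5L)
})

test_that("k-mer counts match manual sliding-window enumeration", {
  tab <- count_kmers(as_reduced_seq("BBBWWBBWB"), 3)
  expect_identical(tab$counts[sort(names(tab$counts))],
                   c(BBB = 1L, BBW = 2L, BWB = 1L, BWW = 1L,
                     WBB = 1L, WWB = 1L))
  expect_identical(tab$window_total, 7L)
})

test_that("sequences shorter than k give an empty table, invalid k rejects", {
  tab <- count_kmers(as_reduced_seq("BB"), 3)
  expect_length(tab$counts, 0L)
  expect_identical(tab$window_total, 0L)
  expect_error(count_kmers(as_reduced_seq("BB"), 0), "k must be")
})

test_that("gap sets enumerate all C(k,g) position subsets in order", {
  expect_identical(enumerate_gap_sets(3, 1), list(0L, 1L, 2L))
  expect_length(enumerate_gap_sets(2, 1), 2L)
  expect_identical(enumerate_gap_sets(4, 0), list(integer(0)))
  expect_identical(enumerate_gap_sets(3, 3), list(0:2))
  expect_error(enumerate_gap_sets(3, 4), "exceed")
  for (k in 1:6) for (g in 0:k)
    expect_length(enumerate_gap_sets(k, g), choose(k, g))
})

test_that("gapped 3-mers of the worked example are the 12 listed patterns", {
  tab <- count_gapped(as_reduced_seq("LBBBWWG"), 3, 1)
  listed <- c("_BB", "_BW", "_WW", "_WG", "L_B", "B_W", "W_G", "B_B",
              "LB_", "BB_", "BW_", "WW_")
  expect_identical(sort(names(tab$counts)), sort(listed))
  expect_identical(tab$window_total, 15L)  # 5 windows x 3 gap positions
})

test_that("g = 0 gapped counting specializes to plain k-mer counting", {
  set.seed(7)
  for (i in 1:10) {
    r <- random_reduced_seq(sample(5:60, 1))
    k <- sample(1:4, 1)
    expect_same_counts(count_gapped(r, k, 0), count_kmers(r, k))
  }
})

test_that("gapped counts conserve total mass C(k,g) * (l - k + 1)", {
  set.seed(11)
  for (i in 1:12) {
    l <- sample(8:80, 1)
    r <- random_reduced_seq(l)
    for (k in 1:6) {
      if (l < k) next
      for (g in 0:k) {
        tab <- count_gapped(r, k, g)
        expect_identical(sum(tab$counts),
                         as.integer(choose(k, g) * (l - k + 1)))
        expect_identical(sum(tab$counts), tab$window_total)
      }
    }
  }
})

test_that("windows touching a skipped residue are excluded consistently", {
  r <- reduce_sequence("RIAXVYPG", policy = "skip")
  tab <- count_kmers(r, 3)
  # X sits at position 4; of the six 3-windows only those starting at
  # 1, 5 and 6 avoid it
  expect_identical(tab$window_total, 3L)
  g1 <- count_gapped(r, 3, 1)
  expect_identical(g1$window_total, 9L)
})

test_that("full_dimension matches the closed form C(k,g) t^(k-g)", {
  expect_identical(full_dimension(6, 3, 1), 108L)
  expect_identical(full_dimension(6, 2, 1), 12L)
  expect_identical(full_dimension(6, 4, 2), 216L)
  expect_identical(full_dimension(6, 5, 3), 360L)
  expect_identical(full_dimension(6, 6, 4), 540L)
  expect_identical(full_dimension(6, 3, 0), 216L)  # t^k when g = 0
  expect_identical(full_dimension(5, 4, 4), 1L)    # all-gap degenerate
  expect_error(full_dimension(0, 3, 1), "t must be")
})
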