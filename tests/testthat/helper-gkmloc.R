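# shared fixtures: random reduced sequences and an independent brute-force
# gapped counter used as the oracle for the trie path

six_alpha <- c("L", "B", "W", "P", "G", "C")

random_reduced_seq <- function(len, alphabet = six_alpha) {
  as_reduced_seq(paste(sample(alphabet, len, replace = TRUE), collapse = ""))
}

# independent oracle: enumerate windows and gap sets with nested loops and
# plain string surgery, no shared code with count_gapped / the trie
brute_gapped <- function(symbols, k, g, gap = "_") {
  l <- nchar(symbols)
  out <- character(0)
  if (l >= k) {
    sets <- if (g == 0) list(integer(0)) else
      lapply(seq_len(ncol(utils::combn(0:(k - 1), g))),
             function(j) utils::combn(0:(k - 1), g)[, j])
    for (s in seq_len(l - k + 1)) {
      win <- substr(symbols, s, s + k - 1)
      for (gs in sets) {
        w <- strsplit(win, "")[[1]]
        w[gs + 1] <- gap
        out <- c(out, paste(w, collapse = ""))
      }
    }
  }
  table(out)
}

counts_equal <- function(a, b_tab) {
  an <- sort(names(a$counts))
  bn <- sort(names(b_tab))
  identical(an, bn) &&
    all(as.integer(a$counts[an]) == as.integer(b_tab[an]))
}

expect_same_counts <- function(a, b) {
  an <- sort(names(a$counts))
  bn <- sort(names(b$counts))
  expect_identical(an, bn)
  expect_equal(unname(a$counts[an]), unname(b$counts[an]))
  expect_identical(a$window_total, b$window_total)
}

# tiny separable 2-class blobs for SVM sanity checks
make_blobs <- function(n_per = 10, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2) + gap, ncol = 2))
  y <- rep(c("a", "b"), each = n_per)
  list(x = x, y = y)
}
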