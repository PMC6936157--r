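# Gapped k-mer counting by direct sliding-window enumeration.  A gapped
# k-mer is a length-k word with g positions replaced by the gap symbol; every
# overlapping window contributes once per gap-position set, so total counts
# equal C(k,g) * (number of valid windows).

#' Construct a count table
#' @keywords internal
gkm_counts <- function(counts, k, g, window_total) {
  counts <- counts[counts > 0]
  structure(list(counts = counts, k = as.integer(k), g = as.integer(g),
                 window_total = as.integer(window_total)),
            class = "gkm_counts")
}

#' @export
print.gkm_counts <- function(x, ...) {
  cat(sprintf("<gkm_counts k=%d g=%d windows*gapsets=%d patterns=%d>\n",
              x$k, x$g, x$window_total, length(x$counts)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

# Character matrix of the valid (skip-free) windows of a reduced sequence:
# one row per window, k columns.  NULL when no valid window exists.
window_matrix <- function(rseq, k) {
  stopifnot(inherits(rseq, "reduced_seq"))
  l <- rseq$length
  if (l < k) return(NULL)
  chars <- strsplit(rseq$symbols, "", fixed = TRUE)[[1]]
  starts <- seq_len(l - k + 1L)
  wm <- vapply(seq_len(k) - 1L, function(j) chars[starts + j],
               character(length(starts)))
  wm <- matrix(wm, nrow = length(starts), ncol = k)
  ok <- rowSums(wm == SKIP_MARKER) == 0L
  if (!any(ok)) return(NULL)
  wm[ok, , drop = FALSE]
}

paste_rows <- function(wm) {
  do.call(paste0, lapply(seq_len(ncol(wm)), function(j) wm[, j]))
}

#' Count k-mers of a reduced sequence
#'
#' Counts every overlapping length-k window (step 1) that does not touch a
#' skipped residue.  For clean input of length l the number of windows is
#' l - k + 1; a sequence shorter than k yields an empty table.
#'
#' @param rseq a `reduced_seq` ([reduce_sequence()] or [as_reduced_seq()]).
#' @param k word length, integer >= 1.
#' @return a `gkm_counts` object: named counts (patterns with count > 0 only),
#'   `k`, `g = 0`, and `window_total` = number of counted windows.
#' @examples
#' count_kmers(as_reduced_seq("LBBBWWG"), 3)  # 5 distinct 3-mers
#' @export
count_kmers <- function(rseq, k) {
  k <- check_k(k)
  wm <- window_matrix(rseq, k)
  if (is.null(wm))
    return(gkm_counts(integer(0), k, 0L, 0L))
  tab <- table(paste_rows(wm))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  gkm_counts(counts, k, 0L, nrow(wm))
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("k must be an integer >= 1")
  as.integer(k)
}

check_g <- function(k, g) {
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g != floor(g))
    stop("g must be a non-negative integer")
  if (g > k) stop("g must not exceed k")
  as.integer(g)
}

#' Enumerate gap-position sets
#'
#' All C(k,g) size-g subsets of the 0-based positions \{0, ..., k-1\}, in
#' lexicographic order.  Gap positions are arbitrary combinations, not only
#' contiguous runs.
#'
#' @param k word length.
#' @param g number of gaps, 0 <= g <= k.
#' @return list of integer vectors (0-based positions); `list(integer(0))`
#'   for g = 0.
#' @examples
#' enumerate_gap_sets(3, 1)  # {0}, {1}, {2}
#' @export
enumerate_gap_sets <- function(k, g) {
  k <- check_k(k)
  g <- check_g(k, g)
  if (g == 0L) return(list(integer(0)))
  if (g == k) return(list(0:(k - 1L)))
  cols <- utils::combn(0:(k - 1L), g)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

# Gapped patterns of the valid windows for one gap set (0-based positions).
gap_patterns <- function(wm, gap_set, gap_symbol = "_") {
  if (length(gap_set)) wm[, gap_set + 1L] <- gap_symbol
  paste_rows(wm)
}

#' Count gapped k-mers by sliding window
#'
#' For every valid window and every gap-position set, the window with those
#' positions replaced by the gap symbol contributes one count.  Total counts
#' therefore equal C(k,g) times the number of valid windows.  With g = 0 the
#' result is identical to [count_kmers()].
#'
#' @inheritParams count_kmers
#' @param g number of gap positions, 0 <= g <= k.
#' @param gap_symbol gap character, default `"_"`.
#' @return a `gkm_counts` with `window_total` = valid windows * C(k,g).
#' @examples
#' count_gapped(as_reduced_seq("LBBBWWG"), 3, 1)  # 12 distinct patterns
#' @export
count_gapped <- function(rseq, k, g, gap_symbol = "_") {
  k <- check_k(k)
  g <- check_g(k, g)
  wm <- window_matrix(rseq, k)
  if (is.null(wm))
    return(gkm_counts(integer(0), k, g, 0L))
  pats <- unlist(lapply(enumerate_gap_sets(k, g),
                        function(gs) gap_patterns(wm, gs, gap_symbol)))
  tab <- table(pats)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  gkm_counts(counts, k, g, length(pats))
}

#' Dimension of the full gapped k-mer feature space
#'
#' The number of distinct gapped patterns over a t-letter class alphabet is
#' C(k,g) * t^(k-g); with g = 0 this is the plain k-mer dimension t^k.  The
#' all-gap pattern (g = k) is permitted by the formula (one degenerate
#' pattern).
#'
#' @param t alphabet size, >= 1.
#' @param k word length.
#' @param g number of gaps.
#' @return integer dimension.
#' @examples
#' full_dimension(6, 3, 1)  # 108
#' @export
full_dimension <- function(t, k, g) {
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != floor(t))
    stop("t must be an integer >= 1")
  k <- check_k(k)
  g <- check_g(k, g)
  as.integer(round(choose(k, g) * t^(k - g)))
}
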