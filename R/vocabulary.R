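# Vocabularies and feature vectors.  Two dimension-reduction measures are
# supported: restricting to patterns observed in the training corpus
# ("observed" mode) and the closed-form full space of C(k,g)*t^(k-g)
# patterns ("full" mode).  Ordering is lexicographic in the C locale, which
# places the gap symbol "_" after the uppercase class symbols — fixed so
# feature matrices are reproducible.

#' Build a pattern vocabulary
#'
#' @param tables list of `gkm_counts` sharing the same k and g (may be empty
#'   in `full` mode).
#' @param mode `"observed"` (sorted union of patterns present in `tables`) or
#'   `"full"` (every pattern from all gap sets crossed with the alphabet).
#' @param alphabet character vector of class symbols; required for `full`
#'   mode. Defaults to the six-class alphabet.
#' @param k,g word length and gap count; taken from `tables` when supplied.
#' @param gap_symbol gap character, default `"_"`.
#' @return an object of class `gkm_vocabulary`: `patterns` (ordered, no
#'   duplicates), `mode`, `k`, `g`, `alphabet`.
#' @examples
#' tab <- count_gapped(as_reduced_seq("LBBBWWG"), 3, 1)
#' length(build_vocabulary(list(tab), "observed")$patterns)  # 12
#' @export
build_vocabulary <- function(tables = list(), mode = c("observed", "full"),
                             alphabet = NULL, k = NULL, g = NULL,
                             gap_symbol = "_") {
  mode <- match.arg(mode)
  if (length(tables)) {
    ks <- vapply(tables, function(tb) tb$k, integer(1))
    gs <- vapply(tables, function(tb) tb$g, integer(1))
    if (length(unique(ks)) != 1L || length(unique(gs)) != 1L)
      stop("all count tables must share the same k and g")
    if (!is.null(k) && k != ks[1]) stop("k disagrees with count tables")
    if (!is.null(g) && g != gs[1]) stop("g disagrees with count tables")
    k <- ks[1]; g <- gs[1]
  }
  if (is.null(k) || is.null(g))
    stop("k and g are required when no count tables are given")
  k <- check_k(k); g <- check_g(k, g)
  if (is.null(alphabet)) alphabet <- reduction_scheme()$class_alphabet
  if (mode == "observed") {
    pats <- unique(unlist(lapply(tables, function(tb) names(tb$counts))))
    if (is.null(pats)) pats <- character(0)
    pats <- sort(pats, method = "radix")
  } else {
    pats <- unlist(lapply(enumerate_gap_sets(k, g), function(gs_) {
      slots <- rep(list(alphabet), k)
      for (p in gs_) slots[[p + 1L]] <- gap_symbol
      # expand.grid varies the first factor fastest; order is fixed by the
      # final radix sort anyway
      grid <- do.call(expand.grid,
                      c(rev(slots), list(stringsAsFactors = FALSE)))
      do.call(paste0, rev(grid))
    }))
    pats <- sort(unique(pats), method = "radix")
  }
  structure(list(patterns = pats, mode = mode, k = k, g = g,
                 alphabet = alphabet, gap_symbol = gap_symbol),
            class = "gkm_vocabulary")
}

#' @export
print.gkm_vocabulary <- function(x, ...) {
  cat(sprintf("<gkm_vocabulary %s k=%d g=%d size=%d (full dim %d)>\n",
              x$mode, x$k, x$g, length(x$patterns),
              full_dimension(length(x$alphabet), x$k, x$g)))
  invisible(x)
}

#' Project a count table onto a vocabulary
#'
#' Patterns in the vocabulary but absent from the table get 0; patterns in
#' the table but outside the vocabulary are dropped (the observed-vocabulary
#' reduction).  Under `frequency` normalization counts are divided by the
#' table's `window_total`, so for a vocabulary covering every observed
#' pattern the values sum to 1.
#'
#' @param table a `gkm_counts`.
#' @param vocab a `gkm_vocabulary` with matching k and g.
#' @param normalization `"counts"` (default; reproduces the printed worked
#'   examples) or `"frequency"` (length-invariant, for classification).
#' @return numeric vector named by the vocabulary patterns.
#' @export
vectorize <- function(table, vocab, normalization = c("counts", "frequency")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(table, "gkm_counts"), inherits(vocab, "gkm_vocabulary"))
  if (table$k != vocab$k || table$g != vocab$g)
    stop("count table and vocabulary disagree on k or g")
  v <- stats::setNames(numeric(length(vocab$patterns)), vocab$patterns)
  hit <- intersect(names(table$counts), vocab$patterns)
  v[hit] <- table$counts[hit]
  if (normalization == "frequency" && table$window_total > 0)
    v <- v / table$window_total
  v
}

#' Gapped k-mer feature matrix for a set of sequences
#'
#' Reduces each sequence, counts gapped k-mers, builds (or reuses) a
#' vocabulary and stacks feature vectors into a matrix, one row per
#' sequence.
#'
#' @param seqs character vector of raw amino-acid sequences (named), a
#'   `labeled_dataset`, or a list of `reduced_seq`.
#' @param k,g word length and gap count.
#' @param mode vocabulary mode, `"observed"` or `"full"`.
#' @param normalization `"counts"` or `"frequency"`.
#' @param scheme reduction scheme for raw input.
#' @param policy unknown-residue policy for raw input.
#' @param vocab optional pre-built vocabulary (e.g. from a training set); when
#'   supplied, `mode` is ignored.
#' @return list with `matrix` (rows = sequences, columns = vocabulary
#'   patterns) and `vocab`.
#' @export
gkm_feature_matrix <- function(seqs, k, g, mode = "observed",
                               normalization = "counts",
                               scheme = reduction_scheme(), policy = "skip",
                               vocab = NULL) {
  if (inherits(seqs, "labeled_dataset"))
    seqs <- reduce_dataset(seqs, scheme, policy)
  else if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- Map(function(s, id) reduce_sequence(s, scheme, policy, id),
                seqs, ids)
  }
  stopifnot(all(vapply(seqs, inherits, logical(1), "reduced_seq")))
  tables <- lapply(seqs, count_gapped, k = k, g = g)
  if (is.null(vocab))
    vocab <- build_vocabulary(tables, mode,
                              alphabet = effective_alphabet(scheme, policy))
  mat <- matrix(0, nrow = length(tables), ncol = length(vocab$patterns))
  for (i in seq_along(tables))
    mat[i, ] <- vectorize(tables[[i]], vocab, normalization)
  rownames(mat) <- names(seqs)
  colnames(mat) <- vocab$patterns
  list(matrix = mat, vocab = vocab)
}
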