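# Multi-tree (trie) counting: k-mer counts live at the leaves of a depth-k
# tree whose arity is the class-alphabet size.  Gapped counts follow by
# deleting the gapped layers and merging (summing) the subtrees beneath
# them, so one trie yields every gap set's counts without re-scanning the
# sequence.

new_trie_node <- function() {
  node <- new.env(parent = emptyenv())
  node$count <- 0L
  node$children <- new.env(parent = emptyenv())
  node
}

#' Build the k-mer multi-tree of a reduced sequence
#'
#' Inserts every valid length-k window into a depth-k trie; root-to-leaf
#' paths spell observed k-mers and leaf counts accumulate window
#' occurrences, so the leaf multiset equals the [count_kmers()] table.  Tree
#' arity follows the alphabet actually observed (binary for a two-symbol
#' sequence, six-ary for the default scheme).
#'
#' @inheritParams count_kmers
#' @return an object of class `gkm_multitree` with fields `root`, `k`,
#'   `n_windows`.
#' @export
build_multitree <- function(rseq, k) {
  k <- check_k(k)
  root <- new_trie_node()
  wm <- window_matrix(rseq, k)
  n <- 0L
  if (!is.null(wm)) {
    n <- nrow(wm)
    for (i in seq_len(n)) {
      node <- root
      for (j in seq_len(k)) {
        sym <- wm[i, j]
        child <- node$children[[sym]]
        if (is.null(child)) {
          child <- new_trie_node()
          assign(sym, child, envir = node$children)
        }
        node <- child
      }
      node$count <- node$count + 1L
    }
  }
  structure(list(root = root, k = k, n_windows = n), class = "gkm_multitree")
}

#' @export
print.gkm_multitree <- function(x, ...) {
  cat(sprintf("<gkm_multitree depth=%d windows=%d leaves=%d>\n",
              x$k, x$n_windows, length(trie_leaf_counts(x)$counts)))
  invisible(x)
}

#' Leaf counts of a multi-tree
#'
#' @param tree a `gkm_multitree`.
#' @return a `gkm_counts` with g = 0, equal to [count_kmers()] on the source
#'   sequence.
#' @export
trie_leaf_counts <- function(tree) {
  collapse_multitree(tree, integer(0))
}

#' Collapse trie layers to obtain gapped counts
#'
#' Removing layer m of the trie and merging the subtrees below it — summing
#' the frequencies of corresponding leaves — yields the counts of patterns
#' gapped at position m; gapping the first position eliminates the head
#' layer and merges the top-level subtrees.  Several layers may be removed
#' at once.  The result equals restricting [count_gapped()] to that single
#' gap-position set.
#'
#' @param tree a `gkm_multitree` from [build_multitree()].
#' @param gap_positions integer vector of 0-based positions to gap; empty
#'   for the plain leaf table.
#' @param gap_symbol gap character, default `"_"`.
#' @return a `gkm_counts` for that gap set (`window_total` = valid windows).
#' @examples
#' tr <- build_multitree(as_reduced_seq("BBBWWBBWB"), 3)
#' collapse_multitree(tr, 1)$counts[["B_B"]]  # 2
#' @export
collapse_multitree <- function(tree, gap_positions, gap_symbol = "_") {
  stopifnot(inherits(tree, "gkm_multitree"))
  gap_positions <- as.integer(gap_positions)
  if (any(gap_positions < 0L | gap_positions >= tree$k))
    stop("gap positions must lie in [0, k)")
  k <- tree$k
  gapped <- logical(k)
  gapped[gap_positions + 1L] <- TRUE
  acc <- new.env(parent = emptyenv())
  walk <- function(node, depth, prefix) {
    if (depth == k) {
      prev <- acc[[prefix]]
      acc[[prefix]] <- if (is.null(prev)) node$count else prev + node$count
      return(invisible(NULL))
    }
    syms <- ls(node$children)
    for (sym in syms) {
      walk(node$children[[sym]], depth + 1L,
           paste0(prefix, if (gapped[depth + 1L]) gap_symbol else sym))
    }
  }
  walk(tree$root, 0L, "")
  pats <- ls(acc)
  counts <- vapply(pats, function(p) as.integer(acc[[p]]), integer(1))
  gkm_counts(counts, k, length(gap_positions), tree$n_windows)
}

#' Gapped k-mer counts via a single trie
#'
#' Builds the k-mer multi-tree once, collapses it for every C(k,g) gap set,
#' and unions the results.  Element-wise identical to [count_gapped()]; the
#' sliding-window counter serves as its independent oracle in the test
#' suite.
#'
#' @inheritParams count_gapped
#' @return a `gkm_counts` with `window_total` = valid windows * C(k,g).
#' @export
gapped_counts_via_trie <- function(rseq, k, g, gap_symbol = "_") {
  k <- check_k(k)
  g <- check_g(k, g)
  tree <- build_multitree(rseq, k)
  gap_sets <- enumerate_gap_sets(k, g)
  parts <- lapply(gap_sets, function(gs)
    collapse_multitree(tree, gs, gap_symbol)$counts)
  all_counts <- unlist(parts)
  if (is.null(all_counts)) all_counts <- integer(0)
  # distinct gap sets yield distinct pattern strings, but sum defensively
  if (anyDuplicated(names(all_counts))) {
    all_counts <- tapply(all_counts, names(all_counts), sum)
    all_counts <- stats::setNames(as.integer(all_counts), names(all_counts))
  }
  gkm_counts(all_counts, k, g, tree$n_windows * length(gap_sets))
}
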