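# Spaced-dipeptide ("XdY") composition over the raw 20-letter alphabet: an
# ordered residue pair separated by exactly d arbitrary residues; d = 0 is
# the classical dipeptide composition.  The vector always has 400 cells,
# indexed alphabetically X-major (AA, AC, AD, ...).

#' Spaced-dipeptide composition vector
#'
#' For each position i with i + d + 1 inside the sequence, the ordered pair
#' (seq\[i\], seq\[i + d + 1\]) increments one of the 400 cells.  Pairs
#' touching a non-standard residue are skipped, so for clean input of length
#' l > d + 1 the counts sum to l - d - 1; when d > l - 2 the vector is all
#' zero.
#'
#' @param seq character scalar, raw amino-acid sequence (uppercased on use).
#' @param d number of spaces between the two residues, integer >= 0.
#' @param normalization `"counts"` (default) or `"frequency"` (divide by the
#'   total pair count).
#' @return an object of class `spaced_dipeptide`: `values` (numeric of
#'   length 400 named by residue pairs), `d`, `normalization`.
#' @examples
#' spaced_dipeptide_vector("AAA", 0)$values[["AA"]]  # 2
#' @export
spaced_dipeptide_vector <- function(seq, d = 0,
                                    normalization = c("counts", "frequency")) {
  normalization <- match.arg(normalization)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d != floor(d))
    stop("d must be a non-negative integer")
  d <- as.integer(d)
  cells <- paste0(rep(STANDARD_AA, each = 20L), STANDARD_AA)
  values <- stats::setNames(numeric(400L), cells)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  l <- length(chars)
  if (l >= d + 2L) {
    i <- seq_len(l - d - 1L)
    x <- chars[i]
    y <- chars[i + d + 1L]
    ok <- x %in% STANDARD_AA & y %in% STANDARD_AA
    if (any(ok)) {
      tab <- table(paste0(x[ok], y[ok]))
      values[names(tab)] <- as.numeric(tab)
    }
  }
  if (normalization == "frequency" && sum(values) > 0)
    values <- values / sum(values)
  structure(list(values = values, d = d, normalization = normalization),
            class = "spaced_dipeptide")
}

#' @export
print.spaced_dipeptide <- function(x, ...) {
  nz <- x$values[x$values > 0]
  cat(sprintf("<spaced_dipeptide d=%d %s nonzero=%d total=%g>\n",
              x$d, x$normalization, length(nz), sum(x$values)))
  if (length(nz)) print(utils::head(nz, 20))
  invisible(x)
}

#' Spaced-dipeptide feature matrix
#'
#' One 400-column row per sequence; a convenience wrapper over
#' [spaced_dipeptide_vector()].
#'
#' @param seqs named character vector of raw sequences or a
#'   `labeled_dataset`.
#' @inheritParams spaced_dipeptide_vector
#' @return numeric matrix, rows = sequences, columns = the 400 ordered pairs.
#' @export
dipeptide_feature_matrix <- function(seqs, d = 0, normalization = "counts") {
  if (inherits(seqs, "labeled_dataset"))
    seqs <- stats::setNames(seqs$records$sequence, seqs$records$id)
  mat <- t(vapply(seqs, function(s)
    spaced_dipeptide_vector(s, d, normalization)$values, numeric(400L)))
  rownames(mat) <- names(seqs)
  mat
}
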