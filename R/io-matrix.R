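# Feature-matrix writers/readers: TSV (header = canonical pattern strings,
# first column = sequence id) and sparse LIBSVM lines
# (`label index:value ...`, 1-based indices into the vocabulary).  Both
# round-trip losslessly for integer counts.

#' Write a feature matrix
#'
#' @param mat numeric matrix, rows = sequences (rownames = ids), columns
#'   named by canonical pattern strings.
#' @param path output file.
#' @param format `"tsv"` or `"libsvm"`.
#' @param labels required for `libsvm`: vector of labels, one per row;
#'   non-numeric labels are written as 1-based indices of their first
#'   appearance.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(mat, path, format = c("tsv", "libsvm"),
                                 labels = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(labels)) stop("libsvm format requires labels")
    if (length(labels) != nrow(mat))
      stop("length of labels does not match number of rows")
    num <- suppressWarnings(as.numeric(labels))
    if (anyNA(num)) num <- match(labels, unique(labels))
    lines <- vapply(seq_len(nrow(mat)), function(i) {
      nz <- which(mat[i, ] != 0)
      feat <- if (length(nz))
        paste(nz, vapply(mat[i, nz], function(v)
                base::format(v, trim = TRUE, scientific = FALSE),
              character(1)),
              sep = ":", collapse = " ")
      else ""
      trimws(paste(base::format(num[i], trim = TRUE, scientific = FALSE),
                   feat))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a TSV feature matrix
#'
#' Inverse of [write_feature_matrix()] with `format = "tsv"`.
#'
#' @param path TSV file with an `id` column and one column per pattern.
#' @return numeric matrix with rownames = ids, colnames = patterns.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$id
  mat
}

#' Summarize dimension reduction achieved by an observed vocabulary
#'
#' Reports observed vocabulary size against the closed-form full dimension
#' C(k,g) * t^(k-g) and the percentage reduction.
#'
#' @param vocab a `gkm_vocabulary`.
#' @return list with `observed`, `full`, `reduction_pct`.
#' @export
dimension_reduction <- function(vocab) {
  full <- full_dimension(length(vocab$alphabet), vocab$k, vocab$g)
  obs <- length(vocab$patterns)
  list(observed = obs, full = full,
       reduction_pct = 100 * (1 - obs / full))
}
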