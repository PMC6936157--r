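# Labeled sequence input.  Labels arrive either as one FASTA per class
# (label = file stem) or as a single FASTA plus a sidecar TSV (id<TAB>label);
# benchmark FASTAs in this field carry inconsistent headers, so labels are
# never parsed out of the description line.

#' Read protein sequences with class labels
#'
#' @param paths character vector of FASTA file paths.  With more than one
#'   path and no label map, each record's label is the file stem.
#' @param label_map optional path to a two-column TSV `id<TAB>label` covering
#'   every record id (required when a single FASTA is given).
#' @return an object of class `labeled_dataset`: `records` (data frame with
#'   columns `id`, `sequence`, `label`) and `classes` (ordered distinct
#'   labels).  Sequences are uppercased and whitespace-stripped; the record
#'   id is the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(paths, label_map = NULL) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("file not found: ", paste(missing, collapse = ", "))
  recs <- list()
  for (p in paths) {
    aa <- Biostrings::readAAStringSet(p)
    if (length(aa) == 0L) stop("empty FASTA file: ", p)
    ids <- sub("\\s.*$", "", names(aa))
    if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", p)
    seqs <- toupper(gsub("\\s", "", as.character(aa)))
    if (any(!nzchar(seqs)))
      stop("empty sequence for id ", ids[which(!nzchar(seqs))[1]], " in ", p)
    recs[[p]] <- data.frame(id = ids, sequence = seqs,
                            label = tools::file_path_sans_ext(basename(p)),
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(label_map)) {
    lm <- utils::read.table(label_map, sep = "\t", header = FALSE,
                            col.names = c("id", "label"),
                            colClasses = "character", quote = "")
    uncovered <- setdiff(records$id, lm$id)
    if (length(uncovered))
      stop("label map missing id(s): ", paste(uncovered, collapse = ", "))
    records$label <- lm$label[match(records$id, lm$id)]
  } else if (length(paths) == 1L) {
    stop("a single FASTA requires a label map (id<TAB>label TSV)")
  }
  labeled_dataset(records)
}

#' Construct a labeled dataset
#'
#' @param records data frame with character columns `id`, `sequence`,
#'   `label`; ids must be unique and sequences non-empty.
#' @return a `labeled_dataset`.
#' @export
labeled_dataset <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "label") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate sequence ids")
  if (any(!nzchar(records$sequence))) stop("empty sequence(s) present")
  structure(list(records = records, classes = unique(records$label)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset n=%d classes=%d>\n", nrow(x$records),
              length(x$classes)))
  print(table(x$records$label))
  invisible(x)
}

#' Write a labeled dataset to FASTA (+ labels TSV)
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed); one FASTA per class plus
#'   `labels.tsv`.
#' @return invisibly, the written file paths.
#' @export
write_fasta_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- dataset$records
  written <- character(0)
  for (cl in dataset$classes) {
    sub <- recs[recs$label == cl, ]
    path <- file.path(dir, paste0(cl, ".fasta"))
    writeLines(paste0(">", sub$id, "\n", sub$sequence), path)
    written <- c(written, path)
  }
  lab <- file.path(dir, "labels.tsv")
  utils::write.table(recs[, c("id", "label")], lab, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(written, lab))
}
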