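# Reduced amino-acid alphabets: map the 20 standard residues onto a small set
# of physicochemical classes so that k-mer spaces shrink from 20^k to t^k.

#' The 20 standard amino-acid one-letter codes
#' @export
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a reduction scheme
#'
#' A reduction scheme is a total map from the 20 standard amino-acid letters
#' to a small alphabet of single-character class symbols.  The default is the
#' six-class physicochemical scheme used throughout this package:
#' hydrophilic `L` = \{R,D,E,N,Q,K,H\}, hydrophobic `B` = \{L,I,V,A,M,F\},
#' neutral `W` = \{S,T,Y,W\}, plus singleton classes `P` (proline),
#' `G` (glycine) and `C` (cysteine).
#'
#' Class symbols deliberately reuse amino-acid letters, so raw and reduced
#' sequences are kept as distinct types ([as_reduced_seq()]) and a reduced
#' sequence is never reduced twice.
#'
#' @param classes named list: class symbol -> character vector of residues.
#'   Defaults to the six-class scheme above.
#' @param name identifier for the scheme.
#' @param gap_symbol single character used for gap positions; must not be a
#'   class symbol. Default `"_"`.
#' @param extra_symbol single character used as the extra class for
#'   non-standard residues under `policy = "extra_class"`. Default `"X"`.
#' @return an object of class `reduction_scheme` with fields `name`,
#'   `mapping` (named character vector residue -> class symbol),
#'   `class_alphabet` (ordered distinct class symbols), `gap_symbol`,
#'   `extra_symbol`.
#' @examples
#' sch <- reduction_scheme()
#' sch$mapping[["R"]]  # "L"
#' @export
reduction_scheme <- function(classes = NULL, name = "six-class",
                             gap_symbol = "_", extra_symbol = "X") {
  if (is.null(classes)) {
    classes <- list(
      L = c("R", "D", "E", "N", "Q", "K", "H"),
      B = c("L", "I", "V", "A", "M", "F"),
      W = c("S", "T", "Y", "W"),
      P = "P",
      G = "G",
      C = "C"
    )
  }
  mapping <- character(0)
  for (sym in names(classes)) {
    res <- toupper(classes[[sym]])
    mapping[res] <- sym
  }
  scheme <- structure(
    list(name = name,
         mapping = mapping,
         class_alphabet = names(classes),
         gap_symbol = gap_symbol,
         extra_symbol = extra_symbol),
    class = "reduction_scheme")
  v <- validate_scheme(scheme)
  if (!v$valid)
    stop("invalid reduction scheme: ", paste(v$diagnostics, collapse = "; "))
  scheme
}

#' Validate a reduction scheme
#'
#' Checks that the mapping covers exactly the 20 standard residues, that every
#' image is a declared class symbol, that class symbols are distinct single
#' characters, and that the gap symbol does not collide with the alphabet.
#' Diagnostic, never throws.
#'
#' @param scheme a `reduction_scheme` (or a bare list with the same fields).
#' @return list with `valid` (logical) and `diagnostics` (character vector of
#'   problems, empty when valid).
#' @export
validate_scheme <- function(scheme) {
  d <- character(0)
  mapping <- scheme$mapping
  alpha <- scheme$class_alphabet
  missing <- setdiff(STANDARD_AA, names(mapping))
  if (length(missing))
    d <- c(d, paste0(paste(missing, collapse = ","), " unmapped"))
  extra <- setdiff(names(mapping), STANDARD_AA)
  if (length(extra))
    d <- c(d, paste0("non-standard residues mapped: ",
                     paste(extra, collapse = ",")))
  dup <- names(mapping)[duplicated(names(mapping))]
  if (length(dup))
    d <- c(d, paste0("duplicated residues: ", paste(unique(dup), collapse = ",")))
  if (any(nchar(alpha) != 1L))
    d <- c(d, "class symbols must be single characters")
  if (anyDuplicated(alpha))
    d <- c(d, "duplicated class symbols")
  bad <- setdiff(unique(mapping), alpha)
  if (length(bad))
    d <- c(d, paste0("mapped symbols not in class alphabet: ",
                     paste(bad, collapse = ",")))
  if (!is.character(scheme$gap_symbol) || nchar(scheme$gap_symbol) != 1L)
    d <- c(d, "gap symbol must be a single character")
  else if (scheme$gap_symbol %in% alpha)
    d <- c(d, "gap symbol collides with a class symbol")
  list(valid = length(d) == 0L, diagnostics = d)
}

#' Read a reduction scheme from a plain-text file
#'
#' One line per class: `<class_symbol><TAB><comma-separated residues>`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @inheritParams reduction_scheme
#' @return a `reduction_scheme`.
#' @export
read_scheme <- function(path, name = basename(path), gap_symbol = "_",
                        extra_symbol = "X") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  classes <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed scheme line: ", ln)
    classes[[parts[1]]] <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  }
  reduction_scheme(classes, name = name, gap_symbol = gap_symbol,
                   extra_symbol = extra_symbol)
}

# Marker used internally for residues skipped under policy = "skip"; any
# window containing it is excluded from counting.
SKIP_MARKER <- "?"

#' Mark a string as an already-reduced sequence
#'
#' Raw amino-acid sequences and reduced sequences share letters, so the two
#' are kept as distinct types; gapped k-mer counters accept only
#' `reduced_seq` objects.  Use this constructor for strings that are already
#' on the class alphabet (e.g. worked examples).
#'
#' @param symbols character scalar over the class alphabet.
#' @param source_id optional sequence identifier.
#' @return an object of class `reduced_seq` with fields `symbols`,
#'   `source_id`, `length`.
#' @examples
#' as_reduced_seq("LBBBWWG")
#' @export
as_reduced_seq <- function(symbols, source_id = NA_character_) {
  stopifnot(is.character(symbols), length(symbols) == 1L)
  structure(list(symbols = symbols, source_id = source_id,
                 length = nchar(symbols)),
            class = "reduced_seq")
}

#' @export
print.reduced_seq <- function(x, ...) {
  cat("<reduced_seq", if (!is.na(x$source_id)) x$source_id else "",
      "len", x$length, ">", x$symbols, "\n")
  invisible(x)
}

#' Reduce an amino-acid sequence onto the class alphabet
#'
#' Replaces each standard residue by its class symbol.  Non-standard residues
#' (X, B, Z, U, O, J, ...) are handled per `policy`:
#' \describe{
#'   \item{`skip`}{(default) the residue is marked so that no counting window
#'     containing it contributes; the alphabet stays at exactly t symbols.}
#'   \item{`error`}{reject, naming the residue and its position.}
#'   \item{`extra_class`}{all non-standard residues map to one additional
#'     class symbol (`scheme$extra_symbol`), giving an alphabet of t+1.}
#' }
#'
#' @param seq character scalar, an uppercase amino-acid sequence. A
#'   `reduced_seq` input is rejected: reduction is defined on raw residue
#'   strings only.
#' @param scheme a [reduction_scheme()].
#' @param policy one of `"skip"`, `"error"`, `"extra_class"`.
#' @param source_id optional identifier carried through.
#' @return a `reduced_seq`.
#' @examples
#' reduce_sequence("RIAVYYPG")  # "LBBBWWPG"
#' @export
reduce_sequence <- function(seq, scheme = reduction_scheme(),
                            policy = c("skip", "error", "extra_class"),
                            source_id = NA_character_) {
  if (inherits(seq, "reduced_seq"))
    stop("input is already a reduced sequence; reduction applies to raw residue strings only")
  policy <- match.arg(policy)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(as_reduced_seq("", source_id))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  out <- unname(scheme$mapping[chars])
  unk <- which(is.na(out))
  if (length(unk)) {
    if (policy == "error")
      stop(sprintf("unknown residue '%s' at position %d", chars[unk[1]], unk[1]))
    out[unk] <- if (policy == "skip") SKIP_MARKER else scheme$extra_symbol
  }
  as_reduced_seq(paste(out, collapse = ""), source_id)
}

#' Reduce every sequence of a labeled dataset
#'
#' @param dataset a `labeled_dataset` (see [read_fasta()]).
#' @inheritParams reduce_sequence
#' @return a list of `reduced_seq`, named by record id.
#' @export
reduce_dataset <- function(dataset, scheme = reduction_scheme(),
                           policy = "skip") {
  recs <- dataset$records
  out <- lapply(seq_len(nrow(recs)), function(i)
    reduce_sequence(recs$sequence[i], scheme, policy, source_id = recs$id[i]))
  names(out) <- recs$id
  out
}

#' Effective class alphabet for a policy
#' @keywords internal
effective_alphabet <- function(scheme, policy = "skip") {
  if (identical(policy, "extra_class"))
    c(scheme$class_alphabet, scheme$extra_symbol)
  else scheme$class_alphabet
}
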