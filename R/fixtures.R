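# Seeded generator of labeled protein-like sequences with controllable
# class-discriminating structure: i.i.d. background residues with planted
# class-specific motifs specified on the REDUCED alphabet, each motif symbol
# realized by sampling any residue of that physicochemical class.  The
# signal therefore survives reduction and exercises the
# reduction -> gapped-k-mer -> SVM pathway end to end.  Not a protein
# evolution simulator: no homology, no positional composition structure.

#' Specification for a synthetic labeled dataset
#'
#' Defaults describe a 4-class benchmark-shaped corpus: class sizes
#' 43/30/13/12, lengths uniform on \[80, 200\], uniform background over the
#' 20 standard residues, and one length-3 reduced-class motif per class
#' planted at rate 0.6 (strong signal).  The rate is the per-slot insertion
#' probability after partitioning each sequence into consecutive
#' motif-length slots, so it lies in \[0, 1\] and 0 yields pure background
#' (classes statistically indistinguishable).
#'
#' @param n_per_class named integer vector: class label -> number of
#'   sequences.
#' @param length_range integer vector `c(min, max)`; lengths drawn uniformly.
#' @param background probability vector over the 20 standard residues
#'   (alphabetical order); default uniform.
#' @param motifs named character vector (one per class) over the reduced
#'   class alphabet; `"_"` in a motif means any residue.
#' @param rate per-slot motif insertion probability in \[0, 1\].
#' @param scheme reduction scheme the motifs refer to.
#' @param seed integer seed (mandatory; the generator is fully
#'   deterministic given it).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = c(cyto = 43L, membrane = 30L,
                                         mito = 13L, other = 12L),
                         length_range = c(80L, 200L),
                         background = rep(1 / 20, 20L),
                         motifs = c(cyto = "LLL", membrane = "BBB",
                                    mito = "WWW", other = "PGC"),
                         rate = 0.6,
                         scheme = reduction_scheme(),
                         seed = 1L) {
  stopifnot(length(n_per_class) >= 1L, !is.null(names(n_per_class)),
            all(n_per_class >= 1L),
            length(length_range) == 2L, length_range[1] <= length_range[2],
            length(background) == 20L, all(background >= 0),
            sum(background) > 0,
            rate >= 0, rate <= 1,
            is.numeric(seed), length(seed) == 1L)
  if (!setequal(names(motifs), names(n_per_class)))
    stop("motifs must be named by the same classes as n_per_class")
  ok_syms <- c(scheme$class_alphabet, scheme$gap_symbol)
  for (m in motifs) {
    syms <- strsplit(m, "", fixed = TRUE)[[1]]
    if (!all(syms %in% ok_syms))
      stop("motif '", m, "' uses symbols outside the class alphabet")
    if (length(syms) > length_range[1])
      stop("motif '", m, "' is longer than the minimum sequence length")
  }
  structure(list(n_per_class = n_per_class, length_range = length_range,
                 background = background / sum(background), motifs = motifs,
                 rate = rate, scheme = scheme, seed = as.integer(seed)),
            class = "fixture_spec")
}

# residues belonging to each class symbol (inverse of the scheme mapping)
class_members <- function(scheme) {
  split(names(scheme$mapping), unname(scheme$mapping))
}

#' Generate a synthetic labeled dataset
#'
#' Background residues are drawn i.i.d. from the spec's background
#' distribution; each motif-length slot is then overwritten with a motif
#' realization with probability `rate`, sampling for every motif symbol a
#' uniform residue from that symbol's class (any residue for `"_"`).
#' Byte-identical output for equal specs.
#'
#' @param spec a [fixture_spec()].
#' @return a `labeled_dataset` with ids `<class>_<index>`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  members <- class_members(spec$scheme)
  members[[spec$scheme$gap_symbol]] <- STANDARD_AA
  rows <- list()
  for (cl in names(spec$n_per_class)) {
    msyms <- strsplit(spec$motifs[[cl]], "", fixed = TRUE)[[1]]
    mlen <- length(msyms)
    for (i in seq_len(spec$n_per_class[[cl]])) {
      l <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      chars <- sample(STANDARD_AA, l, replace = TRUE, prob = spec$background)
      if (spec$rate > 0) {
        slot_starts <- seq(1L, l - mlen + 1L, by = mlen)
        planted <- slot_starts[stats::runif(length(slot_starts)) < spec$rate]
        for (s in planted) {
          chars[s:(s + mlen - 1L)] <-
            vapply(msyms, function(sym) sample(members[[sym]], 1L),
                   character(1))
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("%s_%03d", cl, i),
                   sequence = paste(chars, collapse = ""),
                   label = cl, stringsAsFactors = FALSE)
    }
  }
  labeled_dataset(do.call(rbind, rows))
}
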