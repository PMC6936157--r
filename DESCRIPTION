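Package: gkmloc
Title: Gapped k-mer Features over Reduced Amino-Acid Alphabets for
    Protein Subcellular Localization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes protein sequences as gapped k-mer count vectors over a
    six-class physicochemical reduction of the amino-acid alphabet, with an
    exact multi-tree (trie) counting algorithm that derives all gapped counts
    from a single k-mer trie by layer collapse, plus spaced-dipeptide (XdY)
    composition features.  Includes a one-versus-one RBF support-vector-machine
    evaluation pipeline with grid search, jackknife (leave-one-out) testing and
    per-class sensitivity, specificity and Matthews correlation coefficient, a
    seeded generator of labeled synthetic protein sequences with planted
    class-specific motifs, and FASTA/TSV/LIBSVM input-output with a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
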