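---
title: "Gapped k-mer features over a reduced amino-acid alphabet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped k-mer features over a reduced amino-acid alphabet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkmloc)
```

## The encoding

`gkmloc` encodes a protein sequence in three steps.

**Reduction.** Each of the 20 standard residues is replaced by one of t = 6
physicochemical class symbols: hydrophilic `L` (R, D, E, N, Q, K, H),
hydrophobic `B` (L, I, V, A, M, F), neutral `W` (S, T, Y, W), and the
singleton classes `P`, `G` and `C`.  Class symbols intentionally reuse
amino-acid letters, which makes a reduced string indistinguishable from a
raw one by inspection; the package therefore keeps the two as distinct
types (`reduce_sequence()` produces a `reduced_seq`, `as_reduced_seq()`
asserts one) and rejects reduction of an already-reduced object, so a
silent double reduction cannot occur.

**Gapped k-mer counting.** A gapped k-mer is a length-k word over the
class alphabet with g positions replaced by the gap symbol `_`.  Gap
positions are arbitrary combinations of the k slots, not only contiguous
runs, giving C(k,g) gap sets per window.  Every overlapping window of a
clean length-l sequence contributes once per gap set, so counts total
C(k,g)·(l−k+1) and the full feature space has dimension C(k,g)·t^(k−g)
(t^k when g = 0; plain k-mers are the g = 0 special case).  The all-gap
pattern (g = k) is admitted by the formula — a single degenerate feature
equal to the window count — and is counted but rarely useful.

**Vectorization.** Counts are projected onto a vocabulary: either the
`full` closed-form space or the `observed` union of patterns seen in a
training corpus (typically far smaller; `dimension_reduction()` reports
the shrinkage).  Ordering is lexicographic in the C locale, where `_`
sorts after the uppercase class symbols; no ordering is canonical in the
field, but a fixed one is required for reproducible matrices.  Values are
raw counts by default — this reproduces the package's printed worked
examples exactly — with `frequency` (count / total window–gap pairs) as
the length-invariant option recommended for classification; whether
counts or frequencies are the "right" SVM input is genuinely open, so
both are first-class.

## The multi-tree counting algorithm

`build_multitree()` inserts every window of the reduced sequence into a
depth-k trie whose arity is the alphabet size; leaf counts are exactly the
k-mer counts.  For any gap set, `collapse_multitree()` deletes the gapped
layers and merges the subtrees beneath them, summing the counts of leaves
that become indistinguishable.  Gapping the first position is the special
case of eliminating the head layer and merging the top-level subtrees.
The correctness argument is the marginalization identity: the count of a
pattern gapped at position m equals the sum over all class symbols a of
the count of that pattern with a at m.  The test suite asserts this
identity directly, and holds `gapped_counts_via_trie()` element-wise equal
to the sliding-window counter `count_gapped()` — an independent oracle,
since the two share no code — over 1,000 random sequences spanning
alphabet sizes {2, 6}, lengths 10–500, k ≤ 6 and all g ≤ k.

One trie serves every gap set, so the trie route scans the sequence once
where direct enumeration scans it C(k,g) times; at the problem sizes used
here both are fast, and the value of the dual implementation is chiefly
that each checks the other.

## Spaced dipeptides

`spaced_dipeptide_vector()` counts ordered residue pairs separated by
exactly d arbitrary residues over the raw 20-letter alphabet.  The vector
always has 400 cells, indexed alphabetically X-major (AA, AC, AD, …) —
the ordering is not canonical anywhere, so it is fixed here for
reproducibility.  d = 0 is the classical dipeptide composition, which the
tests cross-check against a naive bigram counter.  For clean input of
length l the counts sum to l−d−1; d > l−2 yields the zero vector rather
than an error, since a short sequence is a legitimate input.  Each vector
carries a single d (concatenating several d values is a command-line
convenience, off by default).

## Handling non-standard residues

Sequences containing X, B, Z, U, O or J are handled by policy.  The
default, `skip`, marks the residue so that **no window containing it is
counted** and excludes those windows from the conservation total; this
keeps the alphabet at exactly t = 6 so the closed-form dimensions hold.
`error` rejects the sequence, naming residue and position.  `extra_class`
maps all non-standard residues to one additional symbol, growing the
alphabet to t+1 — the variant to use when dirty windows should still
contribute.  The same skipping rule applies to spaced-dipeptide pairs.

## The evaluation pipeline

The classifier is a one-versus-one SVM with an RBF kernel: k classes
yield k(k−1)/2 pairwise binary classifiers voting on each test point.
This is delegated to libsvm via `e1071::svm()`, whose multiclass scheme
is natively one-versus-one; features are passed unscaled (`scale =
FALSE`) so the chosen normalization is the only transformation applied.

`grid_search()` scores C and γ over the integer powers of two in
[2⁻⁵, 2⁵] — 11 × 11 = 121 pairs; the spacing inside that range is not
canonical, and integer exponents are the conventional choice — by
stratified, seeded 10-fold cross-validation.  Ties are broken toward the
smallest C, then the smallest γ (preferring the widest margin and the
smoothest kernel among equals, and making degenerate inputs
deterministic).

`jackknife_evaluate()` predicts each of the N samples from a model
trained on the other N−1.  By default (C, γ) is selected **once** on the
full dataset and reused in every fold, mirroring the two-stage protocol
this pipeline models; the held-out point thereby participates in
parameter selection, a documented optimistic bias.  `nested = TRUE`
repeats the grid search inside every fold for an unbiased (and ~N times
slower) estimate.  Both modes are exposed because neither is canonical
for this family of benchmarks.

Metrics come from the pooled jackknife confusion matrix, each class
scored one-vs-rest: Sn = TP/(TP+FN), Sp = TN/(TN+FP), OA = Σ TPᵢ/N, and
MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP)), defined as 0 when
the denominator vanishes (the degenerate-predictor case).  The multiclass
reduction to one-vs-rest is itself a design choice: no multiclass MCC
variant is canonical here, and one-vs-rest keeps each class's score
interpretable in isolation.  A class with a single member can never be
predicted correctly in a jackknife (its only example is held out while
the class is absent from training); the pipeline proceeds and reports the
inevitable error rather than refusing.

## The synthetic-data generator

`generate_fixture()` emulates the *shape* of classical localization
benchmarks without their content: the default spec draws 4 classes of
43/30/13/12 sequences (the class profile of the smallest classical
benchmark), lengths uniform on [80, 200] — within the range of compact
globular proteins — and i.i.d. background residues, uniform over the 20
standard letters.  Class signal is planted as motifs specified on the
**reduced** alphabet, one length-3 motif per class, each motif symbol
realized by sampling a uniform residue from that physicochemical class;
the signal therefore survives reduction and exercises the actual
reduction → gapped-k-mer pathway rather than bypassing it.  Insertion is
slot-based: each sequence is partitioned into consecutive motif-length
slots and each slot is overwritten with probability `rate`, so `rate`
lies in [0, 1], 0 gives pure background (classes indistinguishable;
jackknife OA falls to the majority/chance level) and the default 0.6 is
a strong signal under which the pipeline should recover classes almost
perfectly.  Everything is deterministic given the mandatory seed.

What passing tests on these fixtures shows: that the pipeline extracts
class-discriminating composition when it exists on the reduced alphabet
at benchmark-sized N.  What it does not show: performance on real
proteins, whose signal is weaker, positionally structured (targeting
peptides sit at termini), homology-correlated and compositionally
non-i.i.d.  Accuracy figures on fixtures are properties of the generator,
not predictions of benchmark accuracy.

## Numerical and scale choices

Counting is exact integer arithmetic throughout; the only floating-point
steps are frequency normalization and the SVM.  MCC is computed in double
precision with the product split across two square roots to avoid integer
overflow on large N.  Degenerate inputs are defined rather than rejected
wherever a sensible value exists: l < k gives an empty count table,
empty sequences give empty tries, d beyond the last pair gives a zero
vector.

Problem sizes in the test suite were chosen to make the checks sharp but
cheap: the trie-vs-window equivalence runs 1,000 random sequences (its
full intended scale) in well under two minutes; conservation is checked
exhaustively for k ≤ 6 over random sequences; the SVM recovery check uses
the default 98-sequence fixture with one full grid search, and the
motif-rate monotonicity check uses 40-sequence corpora at rates
{0, 0.3, 0.6} over two seeds with fixed SVM parameters, allowing one
inversion as stochastic slack.

## Known limitations

- The reduction scheme is supplied, not derived; no automatic construction
  from physicochemical property matrices.
- Nucleotide alphabets are structurally possible but untested.
- No streaming or approximate counting; sequences are held in memory.
- The default jackknife protocol is optimistically biased (see above);
  use `nested = TRUE` when an unbiased estimate matters.
- The generator is not a protein evolution simulator: no homology
  structure, no positional composition.
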