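---
title: "Predicting missense pathogenicity from peptide molecular graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting missense pathogenicity from peptide molecular graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnapred)
```

## The modeling idea

A single amino-acid substitution (AAS) changes the local chemistry of a
protein. `mnapred` treats that change the way a cheminformatician would:
the peptide window centred on the substituted residue is converted to an
explicit molecular graph (a structural formula with hydrogens), the graph
is summarized by canonical atom-neighborhood descriptors, and a Bayesian
classifier trained on known pathogenic and benign substitutions in the
same protein scores the query. The approach is a
sequence-structure-property model: sequence in, chemical structure as the
intermediate representation, clinical property out.

This puts variant classification into the well-tested machinery of
activity-spectrum prediction (the PASS family of tools): Multilevel
Neighborhoods of Atoms (MNA) descriptors plus a modified naive-Bayes
classifier whose outputs are two probabilities, Pa ("pathogenic") and Pi
("benign"), reported as Confidence = Pa − Pi. A positive Confidence
classifies the substitution as pathogenic; magnitude expresses how firmly
the query sits inside the pathogenic score distribution.

## From sequence to molecular graph

For a protein of sequence $s$ and a substitution at 1-based position $p$
with alternate residue $a$, the peptide window of odd length $PL$ is the
substring of $\lfloor PL/2 \rfloor$ residues on each side of $p$, with the
substitution applied at the centre. Near a sequence edge the deficit on
the short side is compensated on the other side, so the window keeps
length $PL$ whenever the protein allows; only proteins shorter than $PL$
yield truncated windows. Keeping the window length fixed keeps the
descriptor vocabulary comparable across training examples, which matters
for a counting classifier.

The window is assembled into a molecular graph from per-residue heavy-atom
templates (shipped as `inst/extdata/residue_templates.json`): residues are
chained by peptide C′–N bonds, each bond condensing out the hydroxyl
oxygen of the upstream carboxyl group, and hydrogens are materialized up
to standard valences (C 4, N 3, O 2, S 2) using the templates' Kekulé
bond orders. Fixed, documented protonation states are used: free neutral
termini (H₂N–…–COOH), Asp/Glu as COOH, Lys as NH₂, Arg as neutral
guanidine, His as the Nε–H tautomer. These are the simplest chemically
valid closures; charge states and capping are deliberately not modeled,
and there is no 3D geometry — the descriptors below are purely
topological. Training sets can be exported to and read from MDL SD
(V2000) files with zero-filled placeholder coordinates.

## MNA descriptors

The level-0 MNA descriptor of an atom is its element label. The level-$k$
descriptor is

$$D_k(a) = \mathrm{label}(a)\,\big(\,\mathrm{sort}\{D_{k-1}(b) : b \sim a\}\,\big),$$

the label followed by the lexicographically sorted level-$(k{-}1)$
descriptors of all bonded neighbours, duplicates kept. Hydrogens appear as
neighbours but are never descriptor centres. The descriptor set of a graph
at level $k$ is the deduplicated set of $D_k$ over heavy-atom centres —
the classifier's feature representation. Levels 5–15 are used for models.

Two representation choices deserve explanation:

* **Bare element labels, no bond orders.** Levels are defined purely by
  the number of covalent bonds from the centre, so the bonded-neighbour
  relation is the whole input; ring/charge marks and aromaticity
  perception are intentionally out of scope.
* **Fingerprints instead of literal strings.** The canonical text of
  $D_k$ enumerates every backtracking walk of length ≤ $k$ and therefore
  grows exponentially with $k$ — level-15 strings for a 31-residue
  peptide are gigabytes. Internally a descriptor is carried as a 128-bit
  Merkle-style fingerprint computed from (label, sorted child
  fingerprints); equal fingerprints correspond to equal canonical strings
  up to a ~$2^{-128}$ collision probability, and the fingerprint is a
  pure function of the descriptor, hence stable across graphs, sessions
  and platforms. The test suite verifies on enumerable small graphs that
  the fingerprint partition coincides exactly with the literal-text
  partition. `mna_descriptor()` and `form = "text"` expose the literal
  strings for inspection.

A model at level $L$ uses exactly the level-$L$ set, not the union of
levels $0..L$; the level is one axis of the model-selection grid, and
keeping levels pure makes the axis interpretable.

## The classifier

Training examples are (descriptor set, label) pairs. For descriptor $d$,
let $n_d$ be the number of training examples containing $d$ and
$n_{d}^{+}$ the number of pathogenic ones. The evidence score of a query
set $Q$ is the mean smoothed log-odds surrogate

$$S(Q) = \frac{1}{|Q|}\sum_{d \in Q} \left(2\,\hat P(\mathrm{path}\mid d) - 1\right),
\qquad \hat P(\mathrm{path}\mid d) = \frac{n_d^{+} + 1}{n_d + 2}.$$

Descriptors unseen in training contribute exactly 0, so $S \in (-1, 1)$.
(The implementation computes each term as $(2n_d^{+}-n_d)/(n_d+2)$, an
algebraically identical form with an integer numerator, which makes
class-swap antisymmetry bit-exact in floating point.)

Pa and Pi are tie-half-weighted empirical CDF functionals of the training
score distributions: Pa is the fraction of pathogenic training scores
below $S$, Pi the fraction of benign training scores above $S$, ties
counted half. This gives Pa, Pi ∈ [0, 1], Confidence = Pa − Pi strictly
monotone in $S$ wherever either ECDF moves, and — because ties get half
weight — makes the in-training accuracy measure exactly the
Mann–Whitney tie-corrected AUC. The half-weight tie convention, the
Laplace smoothing, and the arithmetic-mean pooling are the package's
fixed realization of the "modified naive Bayes" family; the scorer sits
behind a small interface (`sspr_score()`) so alternative pooling schemes
can be added without touching Pa/Pi or validation.

## Validation and model selection

Accuracy is the Invariant Accuracy of Prediction: the probability that a
randomly chosen pathogenic example outscores a randomly chosen benign
one, ties half-weighted — numerically the ROC AUC (`iap()`). Two
cross-validation schemes are provided:

* **Leave-one-out** (`loo_auc()`): each example is scored with its own
  contribution removed from the descriptor counts. The count-decrement
  fast path is algebraically identical to refitting $n$ times and is
  verified bit-exact against the naive refit oracle in the tests.
* **Stratified k-fold** (`kfold_auc()`, default $k=5$): examples are
  sorted canonically by id, shuffled per class under a fixed seed, and
  dealt cyclically into folds with cross-class continuation. This keeps
  fold sizes even, guarantees no training split loses a class whenever
  each class has ≥ 2 members, makes the result independent of input
  order, and reduces exactly to leave-one-out at $k = n$.

Model selection is a grid search over the 14 odd peptide lengths 5–31 and
the 11 MNA levels 5–15 — 154 configurations — scored by leave-one-out
AUC, with ties broken toward the smaller peptide length, then the smaller
level (prefer the simpler model; the selection rule itself only demands
the highest AUC). One documented inconsistency: the source method
description gives both "5 to 31" and "7 to 31" for the length range while
consistently stating 14 datasets and 154 models; only 5–31 yields 14 odd
values, so that range is canonical here.

Threshold metrics (`classification_metrics()`) use Confidence > 0 as the
pathogenic call: balanced accuracy, Matthews correlation (0 when a
marginal is empty), and F-measure.

## Data curation rules

`load_variants()` consumes a flat CSV
(`gene,position,ref,alt,label,allele_frequency`) validated against the
protein sequences; non-missense rows, reference mismatches and
non-standard residues are rejected with row-indexed diagnostics, and
duplicate (gene, position, alt) rows keep their first occurrence. Two
curation rules are implemented:

* **Benign supplementation**: unknown-label variants whose population
  allele frequency *strictly* exceeds the disease frequency are relabeled
  benign ("B+"); equality is not sufficient, and unknowns without a
  frequency stay unknown.
* **Dataset gate**: a training set should contain at least 75 labeled
  missense variants. The library warns; the command-line pipeline
  enforces it (override with `min_variants`).

ClinVar review-status handling, transcript selection and any API access
are out of scope — the loader expects a pre-extracted table.

## The synthetic generator

Real training data for this method are clinical extracts that cannot be
bundled, so the package carries a generator whose defaults define its
reference simulation conditions: a 180-residue random protein; a
45-residue damaging span (positions 61–105) standing in for a critical
functional domain; eight chemically drastic damaging alternates
(P, G, W, C, R, D, K, F); 200 distinct variants; and
ascertainment-style sampling in which 45% of draws come from the
pathogenic rule region. The ascertainment mirrors how curated clinical
sets are collected — pathogenic and benign classes arrive near-balanced
rather than at their population rates. Ground truth is pathogenic iff
(position in span) and (alternate in damaging set); observed labels flip
with probability `label_noise`. Allele frequencies are log-normal by true
class (benign around $10^{-3}$, pathogenic around $10^{-6}$) against a
disease frequency of $10^{-4}$, so the supplementation rule is
exercisable end to end. Setting `ascertainment = NULL` gives uniform
sampling over all (position, alternate) pairs, for which the pathogenic
fraction has a closed form used in the tests.

What passing on these data shows — and does not show: the generator
produces a learnable conjunction of positional context and substitution
chemistry with controllable noise, which exercises every stage of the
pipeline and the expected monotone degradation of AUC with label noise.
It does not emulate homologous-site correlations, domain architecture,
mutational hotspots, or the annotation biases of real ClinVar extracts;
accuracy numbers on synthetic data say nothing quantitative about any
real gene.

Under the reference conditions (seed 1, no noise) the full 154-cell grid
takes under a minute on one core and the selected model's leave-one-out
AUC is in the low 0.9s; these sizes were chosen so that a complete
desk-scale replication — grid, cross-validation, noise sweep — runs in a
few minutes.

## Numerical and degenerate-case conventions

* Score ties in Pa/Pi and in the AUC always get half weight, everywhere,
  so the two agree by construction.
* Leave-one-out requires ≥ 2 examples per class (excluding one must not
  empty a class); grid cells violating this are marked invalid and
  excluded from the argmax; an all-invalid grid is an error.
* Descriptor sets use set semantics: a descriptor repeated within one
  molecule counts once.
* A query consisting only of unseen descriptors scores exactly 0 and
  lands mid-distribution (Pa and Pi read off their ECDFs at 0).
* Model files are versioned JSON; score lists are stored as
  17-significant-digit decimal strings because that (unlike generic JSON
  number printing) round-trips IEEE doubles bit-exactly.
* All randomness (fold shuffles, the generator) is behind explicit integer
  seeds; grid search and leave-one-out are seedless and fully
  deterministic.

## Known limitations

Single binary endpoint per model (no multi-disease spectra); no
cross-gene transfer — each protein gets its own model, as in the source
method; bare-element MNA labels (no ring or charge marks); neutral fixed
protonation; no handling of non-standard residues or indels. The
per-descriptor independence assumption of naive Bayes is knowingly wrong
for overlapping neighborhoods — the ECDF calibration of Pa/Pi is what
keeps the output usable as a ranking despite that.
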