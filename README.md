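# mnapred

Pathogenicity prediction for single amino-acid substitutions (missense
variants) by chemical-structure modeling of the local peptide. `mnapred`
is aimed at variant-effect researchers and tool builders who want a
per-protein, training-data-driven classifier that needs nothing but a
protein sequence and a table of labeled substitutions — no alignments,
no conservation tracks, no structure files.

## Method

For a substitution at position *p* with alternate residue *a*:

1. **Peptide window.** The odd-length window of *PL* residues (5–31)
   centred on *p* is cut from the sequence and the substitution applied;
   near an edge the short side is compensated on the other side so the
   window keeps full length.
2. **Molecular graph.** The window is assembled into an explicit
   structural formula (heavy atoms + hydrogens) from residue templates,
   chained by peptide bonds, with free neutral termini. MDL SD file
   import/export is included.
3. **MNA descriptors.** The graph is summarized by canonical Multilevel
   Neighborhoods of Atoms descriptors: level 0 is the element label,
   level *k* is `label(sorted level-(k−1) descriptors of all bonded
   neighbours)`. The deduplicated level-*L* set over heavy-atom centres
   (L = 5–15) is the feature representation.
4. **PASS-style naive Bayes.** With n_d = training examples containing
   descriptor *d* and n_d⁺ the pathogenic ones, the query score is
   S = mean_d (2·(n_d⁺+1)/(n_d+2) − 1). Pa and Pi are tie-half-weighted
   ECDF functionals of the per-class training scores;
   **Confidence = Pa − Pi**, positive ⇒ pathogenic.
5. **Validation & selection.** Accuracy is the Invariant Accuracy of
   Prediction (= tie-corrected ROC AUC) under leave-one-out (exact
   count-decrement fast path) and stratified 5-fold CV; the (PL, L)
   configuration is selected from the 154-cell grid by highest AUC_LOO.

Curation rules for ClinVar/gnomAD-style inputs are implemented (missense
validation against the sequence, benign supplementation when allele
frequency strictly exceeds the disease frequency, a 75-variant dataset
gate), plus a seeded synthetic generator so the whole pipeline is
testable without downloads. See the methods vignette
(`vignettes/mnapred-methods.Rmd`) for the model's assumptions and
numerical conventions.

## Worked example

```r
library(mnapred)

syn <- generate_synthetic(synthetic_spec(seed = 1))   # 180-aa protein, 200 variants
ex  <- build_training_set(syn$protein, syn$variants, pl = 23, level = 11)
model <- fit_sspr(ex, pl = 23, level = 11)
model
#> <sspr_model> PL 23 / MNA level 11
#>   training: 90 pathogenic, 110 benign; 14523 descriptors

loo_auc(ex, pl = 23, level = 11)
#> <cv_result> loo AUC = 0.9288 on 200 examples

v <- syn$variants[3, ]                                # Q100P, a motif variant
w <- extract_peptide_window(syn$protein, v$position, v$alt, 23)
predict(model, mna_descriptor_set(build_molecular_graph(w), 11))$confidence
#> [1] 0.02272727
```

The model was trained on 90 pathogenic and 110 benign substitutions and
ranks held-out variants with a leave-one-out AUC of 0.93; the query
Q100P gets a positive Confidence (Pa − Pi = +0.023), i.e. it is
classified pathogenic — consistent with its planted ground truth.

The same pipeline is available from the shell
(`inst/exec/mnapred train|grid|predict`); queries use the
`<gene> <position> <substitution>` format and predictions are written as
CSV with gene metadata, Confidence and the deployed model's AUC_LOO.

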