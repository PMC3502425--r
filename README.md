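# medner

Ensemble named-entity recognition of medication information in clinical
text.

Discharge summaries state, for each prescribed drug, a cluster of short
fields: the medication name itself (`m`), its dosage (`do`), mode of
administration (`mo`), frequency (`f`), duration (`du`), and the reason it
was given (`r`).  Extracting these fields is a sequence-labeling problem:
every token of a note receives one of 13 BIO labels (`B-x`/`I-x` for each
of the six field types, plus `O`), and contiguous runs of labels decode
back into field mentions.

`medner` is for clinical-NLP researchers who want a complete, reproducible
implementation of the classic three-system ensemble for this task:

* a **rule-based tagger** — case-insensitive longest-match lexicon lookup
  for drug names and indication terms, plus prioritized token-sequence
  patterns for dosage/mode/frequency/duration surface forms
  (`"x10 days"`, `"p.o."`, `"as needed"`, ...);
* an **SVM tagger** — one-vs-one multiclass SVM over the 13 labels with a
  polynomial kernel (u·v + 1)², cost 1.0, and a ±2 token context window;
  with K observed labels it holds K(K−1)/2 pairwise classifiers, the
  predicted label is the pairwise-vote winner, and decoding is greedy
  left-to-right with the tagger's previous prediction as the *history*
  feature;
* a **linear-chain CRF** — P(**y**|**x**) ∝ exp(Σₜ Σₖ wₖ fₖ(yₜ₋₁, yₜ, t,
  **x**)), with state features (token features × label) and label-bigram
  transitions, trained by L-BFGS on the L2-penalized conditional
  log-likelihood and decoded with Viterbi (forward-algorithm normalizer,
  inspectable via `sequence_probability()`).

Both learners consume six feature families: words, POS tags (deterministic
rule-based fallback tagger, pluggable backend), morphology (prefixes and
suffixes up to 3 characters), orthography (21 surface-shape classes),
semantic tags from the rule system, and history / label-bigram features.

Three voting strategies combine the systems per token:

* **simple majority** — a label two of three systems agree on, otherwise
  the label of the highest-ranked system;
* **local CRF-based voting** — the CRF's label wherever the CRF predicts
  duration or reason (the scarce, unstructured fields), the SVM's label
  elsewhere;
* **local SVM-based voting** — the mirror image.

Evaluation is chunk-level exact-match precision/recall/F with
micro-averaging (conlleval semantics), 10-fold cross-validation over
documents, and an approximate-randomization significance test on
per-document prediction sets.  A seeded synthetic-corpus generator
(list-style and narrative medication sentences with gold annotations in an
i2b2-2009-style dialect) and a configurable label corrupter make every
component testable without access-restricted clinical data.

## Worked example

```r
library(medner)

## a synthetic 30-note corpus with realistic field imbalance
corp <- generate_corpus(synth_config(n_notes = 30, seed = 42))

## rule + SVM + CRF + all three voting strategies, 5-fold CV
ex <- run_experiment(corp, mode = "crossval", k = 5, sigtest_n = 200,
                     seed = 1)
ex
#> <ner_experiment> crossval, 5 fold(s), seed 1
#>
#>     system ALL_P ALL_R ALL_F
#>       rule 99.23 97.36 98.29
#>        svm 97.73 97.36 97.54
#>        crf 98.68 98.87 98.77
#>   majority 99.05 98.87 98.96
#>  local_crf 97.92 97.92 97.92
#>  local_svm 98.50 98.87 98.68
```

The rows are the three single systems and the three ensembles; columns are
micro-averaged precision, recall and F (percent) over all mentions,
pooled across folds.  Majority voting edges out every single system here.
Per-field scores show the class imbalance at work — duration, the rarest
field, is the hardest:

```r
ex$scores$majority
#>  field  tp fp fn precision recall      f
#>    ALL 524  5  6     99.05  98.87  98.96
#>      m 241  1  1     99.59  99.59  99.59
#>     do  93  0  0    100.00 100.00 100.00
#>     mo  72  1  0     98.63 100.00  99.31
#>      f  80  0  0    100.00 100.00 100.00
#>     du   8  1  4     88.89  66.67  76.19
#>      r  30  2  1     93.75  96.77  95.24
```

`ex$sigtests` holds pairwise approximate-randomization tests (observed
micro-F difference, one-sided p for each labeling direction).  The
rule-based system alone:

```r
tokenize("Percocet 1-2 Tablets p.o. Q 4 prn,") |>
  rule_tag(lexicon(c(percocet = "m")))
#> $semantic_tags[[1]]
#> [1] "B-m"  "B-do" "I-do" "B-mo" "B-f"  "I-f"  "I-f"
```

A command-line driver with verbs `generate`, `train`, `predict`, `vote`,
`evaluate`, `sigtest`, `crossval` and `experiment` is installed at
`system.file("scripts", "medner.R", package = "medner")`.

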