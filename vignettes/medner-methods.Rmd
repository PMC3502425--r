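---
title: "Methods: models, ensembles, and evaluation in medner"
author: "medner authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, ensembles, and evaluation in medner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medner)
```

## The task and its data model

Medication information in discharge summaries comes in six field types:
medication name (`m`), dosage (`do`), mode (`mo`), frequency (`f`),
duration (`du`) and reason (`r`).  `medner` treats field recognition as
BIO sequence labeling: each whitespace token of a note gets one of 13
labels (`B-x` begins a field of type `x`, `I-x` continues it, `O` is
outside any field), and maximal `B-x (I-x)*` runs decode to mentions.

Tokens are addressed by 1-based line number and 0-based within-line
offset, with inclusive span ends — the convention of the annotation
dialect this package reads and writes (`parse_annotation_line()` /
`write_annotation_line()`, one line per medication event, absent fields
written as `x="nm"`, and a preserved-but-unevaluated `ln` list/narrative
flag).  Tokenization is deliberately minimal: whitespace splitting with
punctuation left attached (`"prn,"` is one token), sentence breaks at
blank lines and after a period-terminated word followed by a new line or
an uppercase-initial token.  Words of the shape `p.o.` (internal dots)
never trigger a break.  This is a fixed, dependency-free convention; it
is not intended to compete with a trained sentence segmenter, and all
downstream components are agnostic to how sentences were obtained.

Two decoding conventions are fixed once and used everywhere:

* **Orphan repair.** An `I-x` whose predecessor is neither `B-x` nor
  `I-x` starts a new mention (equivalently, `repair_bio()` rewrites it to
  `B-x`).  Voting over independent systems can splice arbitrary label
  transitions, so a total decoding convention is a prerequisite for any
  ensemble output to be scoreable.
* **Tie-break order.** Wherever a deterministic order over labels is
  needed (vote ties, equal SVM votes, equal Viterbi scores) the fixed
  order is field order `m, do, mo, f, du, r` with `B` before `I` and `O`
  last.

## The rule-based system

`rule_tag()` is a lexicon-plus-patterns semantic tagger.  The lexicon
maps lower-cased phrases to field types and is matched greedily,
longest-first, left-to-right, case-insensitively.  Pattern rules are
fixed-length sequences of per-token regular expressions with an integer
priority; stronger (numerically smaller) priorities shadow overlapping
weaker matches, and at equal priority the leftmost-then-longest match
wins.  When lexicon and pattern spans collide, the lexicon wins for
medication (drug names are closed-vocabulary) and patterns win for the
other five fields (which are productive surface patterns, not
vocabulary).  The shipped defaults — about 300 lexicon entries and 26
pattern rules — are plain-text data files and fully user-replaceable.

The tagger returns both decoded mentions (the standalone rule system) and
a per-token semantic-tag sequence consumed by the learners as a feature
family.  The semantic tags are position-qualified (`B-m`, `I-m`, ...,
`O`) rather than bare categories: a dictionary span already knows where
it starts, and passing that information on lets the learners use the rule
system's segmentation, not just its typing.  This is a design choice of
this package; a category-only tagger can be emulated by stripping the
prefixes before passing tags in.

## Feature families

`token_features()` emits, for every window offset $d \in [-w, +w]$
(default $w = 2$):

* the word itself;
* its POS tag — by default from a deterministic ~20-rule fallback tagger
  (closed-class word lists, digit patterns, suffix heuristics,
  capitalization away from sentence-initial position).  The backend is
  pluggable (`pos_tag(sentence, backend = )`), so a trained tagger can be
  substituted; the fallback keeps the default pipeline free of model
  downloads and byte-reproducible;
* morphology: all prefixes and suffixes of length 1..3;
* one of 21 orthographic classes.  The class inventory and its
  first-match-wins order are fixed in `ortho_classes()`: digit shapes
  (`ALL_DIGITS`, `SINGLE_DIGIT`, `DOUBLE_DIGIT`, `REAL_NUMBER`,
  `PERCENT`, `RANGE`, `DIGIT_SLASH`, `ALPHA_DIGIT`, `DIGIT_ALPHA`),
  letter shapes (`DOTTED_ABBREV`, `ALL_CAPS`, `INIT_CAP`, `ALL_LOWER`,
  `MIXED_CASE`), compounds (`HYPHENATED`, `SLASH_WORD`), punctuation
  (`PUNCT_ONLY`, `HAS_PAREN`, `ENDS_COMMA`, `ENDS_PERIOD`) and `OTHER`.
  This concrete table is normative for the package: each token receives
  exactly one class, and the medication-specific digit/percent classes
  come first so `"0.5%"` is `PERCENT` rather than merely punctuated;
* the rule system's semantic tag.

Out-of-sentence window positions contribute a boundary marker feature.
Two further families are learner-specific: the *history* feature (the
label assigned at the previous position — SVM only) and *label-bigram*
features (CRF transition features).  Every feature carries its window
offset in its name, so the feature set of a configuration is a superset
of any configuration with a subset of switches — the property that makes
the 10-row ablation grid (`ablation_grid()`) well-defined.

## The SVM tagger

`svm_tagger()` trains a one-vs-one multiclass SVM: with $K$ labels
observed in training, $K(K-1)/2$ pairwise binary classifiers.  The kernel
is polynomial, $(u \cdot v + 1)^2$, with cost $C = 1.0$ and window ±2 —
the configuration reported as the grid-search optimum for this task
family (degrees 1–5, costs 0.5–5.0 were the searched space; the package
exposes `svm_config()` so the grid is representable, but does not
auto-search it).  Prediction takes the label with the most pairwise
votes; ties fall back to the fixed label order.

The quadratic programming is delegated to libsvm (via `e1071`), whose
multiclass strategy is natively one-against-one.  Vote counting and the
tie-break are implemented in this package from the raw pairwise decision
values, so the decision rule is deterministic and independently testable
against explicit vote tallies.

Decoding is greedy left-to-right: the history feature at position $i$ is
the tagger's own prediction at $i - 1$ (training uses the gold previous
label).  No beam or Viterbi search is layered on top of the SVM scores —
history-feature taggers of this design classically decode greedily, and
the CRF covers the global-decoding design point.  Sentences are decoded
in lock-step (one batched classifier call per within-sentence position),
which makes corpus decoding a handful of calls rather than one per token.

## The CRF

The linear-chain CRF defines

$$P(\mathbf{y}\mid\mathbf{x}) =
  \frac{\exp\big(\sum_{t=1}^{L}\sum_{k=1}^{K} w_k f_k(y_{t-1}, y_t, t,
  \mathbf{x})\big)}
  {\sum_{\mathbf{y}'}\exp\big(\sum_{t=1}^{L}\sum_{k=1}^{K} w_k
  f_k(y'_{t-1}, y'_t, t, \mathbf{x})\big)}$$

with indicator feature functions of two kinds: token features crossed
with the label at $t$ (state features) and label-bigram transitions
$(y_{t-1}, y_t)$.  The first position contributes state features only; no
distinguished start/stop transition weights are modeled.  Training
maximizes the conditional log-likelihood with an L2 penalty
$\tfrac{\lambda}{2}\lVert w\rVert^2$, $\lambda = 1$ by default, by L-BFGS
with at most 200 iterations.  These optimizer settings are package
defaults chosen for robustness on mid-sized corpora, not empirical claims;
both are exposed (`crf_tagger(lambda = , maxit = )`).

Decoding is Viterbi; the normalizer is the forward algorithm in log
space.  The scoring path is deliberately inspectable:
`sequence_probability()` returns $P(\mathbf{y}\mid\mathbf{x})$ for any
labeling, which the test suite checks against exhaustive enumeration of
all $|\mathcal{L}|^L$ sequences on small instances (sum-to-one at
tolerance $10^{-8}$, Viterbi equal to the enumeration argmax).  The
forward/backward/Viterbi/gradient inner loops are compiled (Rcpp); the
objective is driven by `optim(method = "L-BFGS-B")` with a cached joint
objective/gradient evaluation.

## Ensembles

Voting is per token, across outputs aligned on the same tokenization:

* **majority** — a label at least two of the three systems agree on wins;
  under three-way disagreement the label of the highest-ranked system is
  used.  The ranking is "the system with the highest overall F-score":
  for unseen words a per-word F-score is undefined, so this package
  interprets the rule as a *static system ranking by overall micro-F on
  the training documents of the fold*, recomputed per fold (capped at 10
  training documents for economy) — and the ranking is also a plain
  configuration input (`voting_config(ranking = )`), so any fixed order
  can be exercised instead;
* **local CRF-based** — the CRF label wherever the CRF predicts duration
  or reason (`B-` or `I-` variants), the SVM label elsewhere.  Duration
  and reason are the scarce fields stated without noun-phrase structure
  ("as long as needed"), where a single model fitted to all six fields
  underperforms; the local strategies route exactly those fields to one
  designated system;
* **local SVM-based** — the mirror image.  The routed field set is
  configurable (`local_fields`), defaulting to `{du, r}`.

After voting, `repair_bio()` runs unconditionally, so every ensemble
output is a valid, decodable BIO sequence.  Voting at the mention level,
weighted/probabilistic voting, and stacking are out of scope.

## Evaluation

`chunk_counts()` implements exact-match chunk evaluation: a predicted
mention is a true positive iff a gold mention with the identical field
type and token span exists; everything else is a false positive or false
negative.  `ner_scores()` turns counts into percent precision, recall and
F (harmonic mean), per field and micro-averaged overall (from summed
counts, so every mention weighs equally); zero denominators score 0.  The
test suite pins this pipeline, through 4 decimal places, to an
independent conlleval-style reference evaluator that works directly on
BIO label columns.

Cross-validation (`make_folds()`) partitions documents into seeded folds
of sizes differing by at most one.  Cross-validated scores are computed
from counts pooled over all folds (micro over the union of test
documents), not as a mean of per-fold F values — the consistent reading
of micro-averaging over all mentions; per-fold predictions remain
available in the experiment object for anyone who wants the other
statistic.

### The approximate-randomization test

For systems A and B evaluated against the same gold, the observed
statistic is $f = F_A - F_B$ (micro-F).  An *entry* is one document's
predicted mention set — the test needs an exchangeable unit, and
per-document sets keep pseudo-systems evaluable against gold; this
definition is fixed here as a design choice.  The j + k entries are
pooled; each iteration draws j entries without replacement as pseudo-A,
leaves the rest as pseudo-B, and computes $f_i$.  The p-value is the raw
proportion of iterations with $f_i - f \ge 0$ (no add-one smoothing — the
plain counting formula).  Two numerical choices:

* draws are generated in **antithetic pairs** (each random partition is
  followed by its complement).  The marginal distribution of each draw is
  unchanged — the complement of a uniformly drawn subset is itself
  uniform — but the realized $f_i$ sample becomes exactly symmetric, so
  identical inputs always give $p \ge 1/2$ rather than fluctuating around
  it;
* the test is one-sided and its direction depends on which system is
  labeled A.  Rather than guessing a convention, both orderings are
  reported (`p_value`, `p_value_reversed`, computed from the same draws).

A per-document *swap* variant (each document's two entries exchanged with
probability ½) is available behind `variant = "swap"` for sensitivity
analysis.  Calibration is tested empirically: under a simulated null (two
corruptions of the same gold with the same error configuration and
different seeds), the rejection rate at $\alpha = 0.05$ over 200
repetitions of 200 shuffles must fall inside the exact 95% binomial
acceptance band around 0.05.

## The synthetic corpus generator

`generate_corpus()` emulates the *shape* of a medication-annotated
discharge-summary corpus:

* **class imbalance** — default per-sentence field rates are proportional
  to the field counts of the published corpus profile this package
  targets (ratios 12773 : 4791 : 3552 : 4342 : 597 : 1534 for
  m : do : mo : f : du : r, normalized by its 9,689 sentences, i.e. 1.318
  medication mentions per sentence down to 0.062 duration mentions per
  sentence).  Duration and reason are therefore scarce in training data —
  exactly the hard-case structure that motivates the local voting
  strategies;
* **event structure** — medication events per sentence are
  Poisson(rate~m~); the other five fields attach to an event
  independently with probability rate~x~/rate~m~ (Poisson thinning), so
  realized per-field counts are Poisson with the configured expectations
  and can be verified at 3σ;
* **list vs narrative style** — list-style sentences are bare field
  sequences ("Drugname 40 mg p.o. daily x10 days"); narrative sentences
  wrap events in prose ("The patient was given ... as needed for
  dizziness").  The narrative inventories deliberately include the
  confusable pair *"as needed"* (frequency) vs *"as long as needed"*
  (duration);
* **drug vocabulary** — synthetic multi-syllable drug names (about 10%
  multi-token), emitted with the generating lexicon, so lexicon-coverage
  experiments are controlled.

Notes are laid out one sentence per line with blank separator lines, so
the tokenizer provably reconstructs the generator's segmentation and gold
offsets — the generator tests corpus-model invariants, not the sentence
splitter.  All randomness flows through R's default Mersenne-Twister
generator under the configured seed; the generator saves and restores the
caller's RNG state.

The `"separable"` profile restricts every phrase inventory to surface
forms fully recoverable by the shipped lexicon and patterns and forces
list style.  On such a corpus the rule system is exact by construction,
and both learners reach ≥ 99% micro-F — the end-to-end recovery surface.
What passing these tests shows is that the pipeline is *correct*:
encoding, features, optimization, decoding, voting and scoring compose
without loss.  What it deliberately does not show is performance on real
clinical text, which has misspellings, section structure, abbreviation
collisions, out-of-lexicon drugs and annotation ambiguity that the
generator does not emulate; published scores on the real
data-use-agreement corpus are not reproducible from synthetic data, and
no claim of that kind is made here.

`corrupt_labels()` turns gold labels into simulated system output with
per-field deletion rates, one-token boundary errors, a type-confusion
matrix and Poisson spurious insertions.  Corruption, evaluation and the
randomization test close a parameter-recovery loop: configured error
rates must be recovered by the evaluator within sampling error.

## Problem sizes and runtime choices

The shipped test suite exercises: 1,000-sentence round-trip suites for
the codecs; the full 13³ voting-triple table and 10⁵ routing pairs; 100
random instances for the CRF enumeration oracle (L ≤ 3, ≤ 5 labels) and
100 random corpora for the evaluator oracle; a 200 × 200 null-calibration
of the significance test on a 25-note corpus; and a 500-note separable
corpus (about 7,600 mentions) for end-to-end recovery with a 60/40 split.
The acceptance script runs 10-fold cross-validation on a 60-note default-
profile corpus and a 200-note separable split.  These sizes are the
package's own balance between statistical resolution and a test suite
that runs in minutes on one core; all of them scale up by changing one
configuration argument.

## Known limitations

* The rule system is a compact lexicon-and-patterns tagger, not a port of
  any full-scale medication-extraction grammar; its coverage on real text
  is bounded by its shipped data files.
* Relation structure (which dosage belongs to which drug) is parsed and
  preserved as event grouping in the annotation dialect but never
  predicted or evaluated; this package addresses the field-recognition
  step only.
* Mentions are contiguous token spans; character-offset (stand-off)
  annotation and nested or overlapping mentions are out of scope.
* The SVM exposes no calibrated probabilities, and its greedy decoding
  admits no lattice constraints; the CRF is the globally normalized model
  of the pair.
* CRF training is batch L-BFGS on in-memory feature indices — adequate
  for corpora of thousands of sentences, not engineered for millions.
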