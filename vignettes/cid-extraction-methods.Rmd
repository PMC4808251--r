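---
title: "Methods: chemical-induced disease relation extraction with cidrex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-induced disease relation extraction with cidrex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidrex)
```

# The problem

Chemical-induced disease (CID) relations — "lithium caused tremor",
"cisplatin-associated nephrotoxicity" — are asserted in article abstracts at
the *document* level: an annotation says that the abstract as a whole
supports the relation between a chemical MeSH concept and a disease MeSH
concept, without pointing at a sentence. Extracting them automatically
therefore requires three coupled capabilities: finding the mentions,
grounding them in MeSH, and deciding which (chemical, disease) concept
pairs the document asserts. `cidrex` implements that pipeline end to end,
along with the evaluation metrics used for such systems and a synthetic
corpus generator that makes every stage testable offline.

# Named entity recognition

## Model

Mentions are recognized with linear-chain conditional random fields over
BIO-encoded token sequences: `B-C`/`I-C` open and continue a chemical,
`B-D`/`I-D` a disease, `O` is outside. Two regimes are supported:

* **separate** (the default): one CRF per entity type, each over a 3-label
  alphabet. Extra corpora annotated for only one type can be added to the
  matching model. Cross-type span conflicts at prediction time are resolved
  in favor of the longer span, ties going to the chemical (a fixed,
  documented rule).
* **unified**: a single CRF over the 5-label alphabet.

No CRF engine is available as an R package dependency here, so the package
carries its own: the C++ core (`src/crf.cpp`) computes the exact negative
log-likelihood and gradient by forward–backward in log space, plus Viterbi
decoding; training minimizes the L2-regularized objective with L-BFGS-B
from a zero initialization. Because the data, the feature vocabulary
(sorted), and the optimizer are all deterministic, training is exactly
reproducible without any random seed entering the computation; the
`seed` field of `ner_config()` is stored for provenance only. Defaults —
L2 strength 1.0, at most 200 L-BFGS iterations — favor reproducibility
over squeezing out the last fraction of likelihood. Emission features may
be real-valued, which is what lets word-embedding dimensions enter the
model directly.

## Features

Five per-token feature groups, each switchable:

1. *word-level*: lowercased word, stem, PoS tag, case-shape pattern
   (upper→`A`, lower→`a`, digit→`0`, others kept, so `Ca2+` → `Aa0+`),
   character 2–4-grams, prefixes and suffixes of length 1–5, and a bias.
2. *dictionary lookup*: a greedy longest-match left-to-right semantic
   tagger over a user-supplied term→tag lexicon, emitting `B-tag`/`I-tag`
   per matched token and `NONE` elsewhere.
3. *contextual*: bi- and tri-grams of word, stem, PoS and semantic tag in a
   ±2-token window (configurable), with positional prefixes and a `<S>`
   boundary symbol; for window *w* this yields a fixed
   4 × ((2w) + (2w − 1)) features per token.
4. *domain affixes and chemical patterns*: configurable disease suffix
   (`-algia`, `-emia`, `-itis`, …) and prefix (`ab-`, `hemo-`, …) flags,
   plus chemical-likeness clues — element and amino-acid name match, a
   formula-shaped-token regex, digit/uppercase/hyphen counts, Greek-letter
   flag. The chemical clue set is this package's own concrete inventory
   for the "characteristics specific to chemicals" style of feature used
   in chemical NER.
5. *embeddings*: one real-valued feature per dimension of a word2vec-format
   vector table, case-folded lookup, zero vector for unknown words. Raw
   per-dimension values were chosen over binning because the CRF supports
   weighted features directly; binning is a documented alternative.

## Text preprocessing

The tokenizer splits on whitespace, then into letter runs, digit runs and
single punctuation marks (so hyphenated chemical names split:
`Lithium-induced` → `Lithium`, `-`, `induced`). Sentence boundaries fall
after `.`, `!` or `?` followed by whitespace. No PoS tagger or stemmer
package is available in the dependency footprint, so both are small
deterministic rule systems owned by the package: a closed-class +
suffix-heuristic tagger (coarse Penn-style tags) and a conservative
suffix-stripping stemmer (plurals, `-ing`, `-ed` with length guards). The
preprocessing of real systems in this area is rarely specified precisely;
what matters for the model is that the pipeline is deterministic and that
the normalization index and queries share it exactly.

Document full text is the title, one space, then the abstract; all offsets
are 0-based with exclusive ends, the convention of the PubTator corpus
format. Mentions that do not align with token boundaries are snapped
outward to the covering tokens at BIO-encoding time; overlapping gold
mentions are resolved by keeping the longer (ties: earlier) because BIO
cannot represent overlap; a stray `I-*` after `O` or after the other type
is decoded as `B-*`, keeping the decoder total.

# Normalization to MeSH

Every name and synonym of every concept becomes a TF-IDF-weighted unit
vector over lowercased stems, with smoothed IDF
`1 + log((N + 1)/(df + 1))` — a term occurring in every name keeps a floor
weight of 1 rather than vanishing. A mention is scored against every name
vector by cosine; a concept's score is the maximum over its names, so
synonyms do not dilute each other. Ties on the top score are broken by the
lexicographically smallest MeSH ID — a deterministic replacement for
arbitrary tie selection, chosen for testability (a seeded random choice
would also be defensible but makes oracle tests weaker). If the mention
shares no token with any name, the pseudo ID `"-1"` is returned with score
0. Chemical and disease mentions are normalized against separate,
type-disjoint indexes.

# Relation extraction

Candidates are the unique (chemical ID, disease ID) pairs of a document
with both IDs normalized; `-1` never generates a pair, and composite
annotations (`D1|D2`) contribute each constituent ID.

**C_S, the sentence-level classifier**, sees one instance per (pair,
sentence) co-occurrence. Training labels come from distant supervision:
an instance is *true* iff its pair is in the document-level gold — a rule
that deliberately tolerates false-positive instances (a pair may co-occur
in a sentence that does not express the relation). At prediction time a
pair is positive if *any* of its sentence instances is positive (any-vote;
the alternative majority vote is weaker exactly when a relation is
expressed in one sentence of several).

**C_D, the document-level classifier**, sees one instance per candidate
pair, labeled by the gold directly.

Features (groups switchable for ablation):

* *entity*: bag-of-words and bigrams of the mention texts (pooled over the
  anchor sentence for C_S, the document for C_D), both MeSH IDs, a
  chemical-first flag (C_S only), and a *core chemical* flag — a chemical
  is core when it appears in the title or is the most frequently mentioned
  chemical of the abstract (ties: all tied chemicals are core).
* *context*: words and bigrams before/between/after the anchored mention
  pair (C_S); sentence-distance one-hots for C_D — same sentence
  (distance 0), adjacent (1), crosses more than two sentences (≥ 2),
  interpreted as a partition so exactly one fires; an induced-trigger
  (`terms_i`: caused, induced, produced, …) match on the between words —
  at document level this between-span may cross sentence boundaries; and a
  holder-term (`terms_h`: patient, groups, rats, …) match in the disease
  sentence, emitted at document level only when the pair is same-sentence
  or adjacent.
* *knowledge*: MeSH hypernym categories of both concepts (all proper
  prefixes of each tree number); whether the document contains a more
  specific or more general disease than the target (via the
  proper-tree-number-prefix test); the pair's relation label (or `null`)
  in MEDI, MEDI high-precision, SIDER, SIDER-FAERS and CTD; `isADR(d)`
  (any adverse-drug-reaction row for the disease in SIDER) and
  `isInduced(d)` (any marker/mechanism row in CTD).

When a pair has several mention pairs, context features anchor on the
mention pair with the smallest token distance (ties: earliest); the
closest co-occurrence is usually the most informative context.

Both classifiers are linear SVMs (libsvm via `e1071`) with cost 1,
balanced class weights and decision threshold 0 — a standard strong
baseline for high-dimensional sparse lexical features, and deterministic
for fixed training data. The final prediction strategy is the **union** of
the two classifiers' positive pairs (also available: `cs` or `cd` alone).
Union is the default because C_S cannot reach cross-sentence relations at
all — roughly 30% of relations in real corpora — while C_D alone is
noisier on same-sentence evidence; their union dominates both in recall by
construction.

# Evaluation

All metrics are micro-averaged P/R/F over set comparisons: mention level
(doc, start, end, type) with exact span matching; concept level
(doc, concept ID), `-1` excluded on both sides; CID level
(doc, chemical ID, disease ID) ordered triples. *Relation coverage* counts
gold relations whose two concepts both appear among the predicted concept
IDs of the document — an upper bound for any downstream classifier. When
both gold and prediction are empty, all three metrics report 1 by
convention, flagged as degenerate and configurable, since official
scorers differ on this corner.

# The synthetic fixture generator

`fixture_spec()` + `make_fixture()` generate, deterministically from a
seed: a pronounceable chemical dictionary and a rooted disease hierarchy
(child names prepend a modifier to the parent name; child tree numbers
extend the parent's, so parent/child disease pairs exercise the
specificity features); KB tables consistent with the planted truth;
semantic lexicons, trigger lists and a small random embedding file; and
PubTator corpora in which every planted-true pair is rendered with an
induced-trigger template — inside one sentence, or across adjacent/distant
sentences for a configurable fraction (default 0.3, matching the
cross-sentence share reported for real corpora) — and every planted-false
co-occurrence with neutral templates.

Design choices worth noting:

* **Pair-intrinsic truth.** Whether a (chemical, disease) pair is true is
  drawn once and reused across all documents where the pair co-occurs.
  KB tables are keyed by pair, so per-document truth would make the same
  CTD row simultaneously confirm and contradict the gold, an incoherence
  real corpora do not exhibit at this scale.
* **Default conditions**, chosen once as a plausible miniature of an
  annotated corpus: 25 chemicals, 30 diseases in a depth-3/branching-3
  hierarchy, 1–2 chemicals and 2–3 diseases per abstract, true-pair
  probability 0.6 for the core chemical and 0.3 otherwise, distractor
  sentence rate 0.3, synonym usage 0.3, out-of-dictionary mention rate
  0.05 per document, CTD recording 70% of true pairs (marker/mechanism)
  and 50% of false pairs (therapeutic), SIDER/MEDI populated analogously
  with their own label alphabets, high-precision/FAERS subsets as 50%
  sub-samples.
* **What the generator does not emulate**: linguistic variety (templates,
  not prose), abbreviations, nested or discontinuous mentions, ambiguous
  names shared between concepts, and realistic MeSH vocabulary
  distributions. Passing the recovery experiments therefore demonstrates
  that the pipeline's machinery — tagging, grounding, distant supervision,
  feature wiring, union combination — is correct and learnable, not that
  real-corpus scores would reach these levels; on real data, NER and
  normalization are far harder, and reported end-to-end scores for
  systems of this design are in the 0.5–0.6 F range.

The bundled experiments (tests and `scripts/acceptance.R`) use a
200-abstract corpus with a 150/50 train/test split — small enough to train
the CRFs and SVMs in well under a minute on one core, large enough that
held-out behavior is stable across seeds. NER there runs in separate mode
with a 120-iteration cap.

# Numerical and degenerate-input choices

* CRF: log-space forward–backward (no underflow), zero initialization,
  `factr = 1e9` L-BFGS tolerance; unseen features at prediction time are
  dropped (zero weight).
* Normalization: cosine ties use a 1e-9 tolerance so that token-identical
  names compare equal under floating point; scores are clamped into
  [0, 1].
* Empty sentences, empty documents, mentions with no covering token,
  unknown MeSH IDs and empty KB tables all degrade to neutral values
  (empty feature sets, `(FALSE, FALSE)` flags, `null` labels) rather than
  errors; genuinely unusable training input (no documents, single-class
  labels, zero positive relations) errors early and explicitly.

# Known limitations

* The rule-based post-processing some challenge systems bolt on is
  deliberately out of scope, as is abbreviation resolution and BioC/XML
  input.
* The heuristic PoS tagger and stemmer are crude; on real corpora a
  mature tagger would likely add a little NER accuracy. They are isolated
  behind `pos_tag()`/`stem_word()` and easy to swap.
* Hyperparameters (CRF L2, SVM cost, window sizes, n-gram inventories) are
  declared defaults, not tuned values; the ablation switches exist
  precisely so users can probe their contribution on their own data.
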