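---
title: "Methods: joint span-based NER and gene-disease relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint span-based NER and gene-disease relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model and the design
decisions behind it. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The data model

The unit of work is an annotated document: text, typed character-span
entity mentions, and typed binary relations between mentions. Twelve entity
types fall into two categories — biological entities (Gene, Disease,
Protein, Variation, Enzyme, MPA, CPA, Interaction, Pathway) and regulatory
expressions (Regulation, PosReg, NegReg). Everything that is not a Gene or
Disease can act as a *trigger word*: an intermediate node through which a
gene-disease association is annotated indirectly. After schema
normalization every relation label is the single symmetric predicate
`LinkedOf` (source corpora using `ThemeOf`/`CauseOf` are mapped onto it,
deduplicating triples that become identical).

Spans are 0-based half-open character offsets — the common standoff
convention; nothing in the annotation model forces one, so we fix it
package-wide and validate `surface == text[start:end]` on every read.

### Direct-edge augmentation

A *direct edge* (DE) joins a gene and a disease that the annotation
connects through a trigger path. The one-trigger case is the canonical
picture; the schema permits trigger-trigger relations, so we generalise to
any-length trigger-interior path within a document (`max_path` caps the
interior length; default unbounded). Direct edges are undirected for
matching and stored gene-first for determinism. Protein mentions are *not*
DE endpoints by default — the augmentation targets gene-disease pairs, and
proteins are handled at entity-linking time by endowing the encoding gene's
identifier — but the endpoint set is a parameter of `add_direct_edges()`
for users who want proteins to anchor edges. The operation is idempotent
and monotone, and the test suite pins it against a brute-force simple-path
oracle.

## The model

**Tokenization.** A byte-pair-encoding tokenizer is trained on the corpus
at hand (default vocabulary 300): characters plus greedy most-frequent
merges, ties broken lexicographically so training is deterministic.
Out-of-vocabulary words decompose into subword pieces; characters unseen in
training map to an unknown id but keep their offsets, so alignment is total.
Gold spans whose boundaries split a subword snap outward to the covering
subwords (the minimal covering token interval), which preserves recall.

**Encoder.** The default encoder is a small trainable transformer: token +
position embeddings, `layers = 2` blocks of `heads = 2` scaled-dot-product
self-attention with residual connections and a tanh feed-forward expansion
(`H = 64`, `ffn = 128`), sized to train in minutes on one CPU. Layer
normalisation is omitted deliberately: at this width and depth, damped
residual initialisation (output projections scaled by 0.5) trains stably,
and the gradient path stays simple enough to verify by finite differences.
Documents longer than the window (`max_len = 512`) are encoded with a
half-window stride and mean-merged overlaps at inference; training assumes
abstract-length inputs. Designs in this family often pair a large
pretrained encoder with a shallow task-specific classifier sub-module; the
package collapses that split and exposes exactly one encoder contract (ids in, `n x H` matrix
out) plus shallow heads, and a pretrained adapter can replace the tiny
encoder behind the same contract.

**Span NER.** Every token interval of width 1..`max_width` is a candidate.
`max_width = 10` subwords: longer sub-sequences are increasingly unlikely
to be entities, and the cap bounds the candidate set at roughly `10 n`. The
representation is the element-wise max-pool over the span's token vectors
concatenated with a learned width embedding (`width_dim = 25`; widths
beyond the table clamp to its last row). A one-hidden-layer tanh classifier
scores 13 classes (12 types + non-entity) and trains with the *summed*
cross-entropy `-sum(y * log p)` — a plain sum, not a mean; a mean reduction is
available but the sum is the default. At training time the observations are
all gold spans plus up to `neg_spans = 100` sampled non-entity spans per
document per pass (scoring every span every step is wasteful; resampling
across epochs covers the space). Argmax ties break
toward the lowest class index; identical predicted spans keep the
higher-probability type.

**Relation extraction.** Candidates are all gene x disease mention pairs in
a document (gene first, deduplicated on span coordinates). The feature
vector concatenates four parts: the two span representations, the max-pool
of tokens strictly between the spans (adjacent or overlapping spans give
the zero vector — the max-pool identity under the empty-pool convention),
and an attention context `sum_i w_i x_i`. The attention weights are a
softmax over scaled dot products: the weighted-sum form is given, the
weight function is not, and scaled-dot softmax is the standard choice that
keeps weights non-negative and normalised (so the context provably lies in
the convex hull of the values — a tested invariant). The query is a linear
projection of the two pooled span vectors; keys and values come from a
sequence encoder over the token vectors, implemented as a bidirectional
tanh recurrent layer (`seq_encoder = "birnn"`), switchable to identity
pass-through where speed matters more than an extra encoding pass. A
two-class softmax head scores each pair; its positive-class probability
feeds a binary cross-entropy. (A two-class softmax whose positive-class
probability enters binary cross-entropy is mathematically the same sigmoid
link as a single-logit head; the two-class form keeps the NER and RE heads
structurally alike.) A pair is predicted linked iff `p_link > 0.5`, strictly: exactly 0.5
is not a link. Training uses gold entity spans for RE candidates (with all
unlinked gene-disease pairs as negatives, capped at `neg_pairs = 50`);
inference uses predicted spans in joint mode and gold spans in onlyRE mode.
Scheduled sampling from predicted spans is not implemented.

**Joint loss and optimisation.** `L = L_NER + L_RE`, an exact sum, with
gradients flowing into both heads and the shared encoder; in onlyRE mode
the NER term is dropped. The optimizer is AdamW (decoupled weight decay
0.01) under a linear warmup over the first 10% of steps followed by linear
decay to zero. The default initial rate 6e-5 is the standard fine-tuning
rate for large pretrained encoders and is kept as the configuration
default; training the tiny encoder *from scratch* at desk scale uses
`lr = 2e-3` throughout the tests and the acceptance script — at 6e-5 the
small model would need hours to leave its initialisation, and 2e-3 with
warmup is stable (5e-3 is not: the summed loss oscillates, which the
training-divergence guard surfaces as a non-finite-loss abort when it goes
further).

All gradients come from a small reverse-mode tape written for this package
(`R/autodiff.R`); correctness is pinned by central-finite-difference checks
down to 1e-4 relative error on an end-to-end three-token document, and to
1e-6 on individual operations.

## Evaluation

Predictions and gold annotations are compared as graphs. Nodes are typed
mentions keyed by (document, span, type); entity matching is exact on both
span and type (the strictest reading; overlap-relaxed matching is a
possible extension, not currently exposed). Edges match undirected. From
the TP/FP/FN counts: precision, recall, F1 (harmonic mean; 0 when TP = 0;
precision of an empty prediction set is reported as 0 rather than NaN so
fold averaging stays total).

Relation evaluation scores against the *direct-edge closure* of the gold
annotation by default: a predicted gene-disease pair is correct if gold
links it directly or through a trigger path. Rationale: training with DE
augmentation changes the labels a model sees, and scoring the two arms
against different target sets would change the task rather than the
training signal. `eval_target = "raw"` scores against the literal
annotation instead; both modes are provided because either convention can
be argued for, and ablations should state which they use.

Cross-validation is document-level k-fold (default k = 5), sizes differing
by at most one with the remainder on the earlier folds; the fold split,
negative sampling and initialisation all derive from one seed through keyed
hashing (`derive_seed`), so ablation arms share byte-identical folds.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the pipeline needs
to be testable offline: twelve entity types with gene+disease mentions
steered to a configurable 40% of all mentions (a composition typical of
manually annotated gene-disease corpora), trigger-mediated link events (gene - trigger [-
trigger] - disease, with a 20% two-trigger chain rate), relation-free
negative documents (15%), and per-type surface lexicons embedded in filler
text. Some surfaces are deliberately shared across types (gene symbols
reused as protein names) so type assignment cannot be solved by lookup, and
the tail of every lexicon can be held out (`split = "test"`) to probe
generalization to unseen surfaces. Each document draws from a substream
keyed by (seed, index), so corpora are stable under resizing and
reordering, and identical configurations serialize byte-identically.

What it does *not* emulate: biomedical language statistics (filler text is
a bag of common words), discontinuous or nested gold mentions, annotation
noise, document-length variation beyond a few sentences, and any
correlation between entity identity and linkage beyond the trigger
structure. Passing tests on this generator therefore demonstrate that the
machinery learns and evaluates correctly at desk scale — not that the tiny
encoder would match fine-tuned pretrained models on real abstracts, which
is explicitly out of scope.

Sizes used by the checks (package choices): overfit sanity trains on 20
documents (250 epochs joint at `lr = 2e-3`, 60 epochs onlyRE) with the
default `H = 64` encoder; the ablation uses 100 documents, 5 folds, 8
epochs per arm with a reduced encoder (`H = 32`, 1 layer, identity sequence
encoder) — the DE effect is a property of the training labels, not of
encoder capacity, and the reduced setting keeps the four-arm run in
minutes. On a corpus whose gold is entirely trigger-mediated, the no-DE
arms see zero positive gene-disease pairs, so their recall is structurally
0; the joint arms at this budget are NER-bound, reproducing ordinally the
reference pattern that gold entities (onlyRE) outperform joint prediction.

## Entity linking, rules, and integration

Linking is cosine similarity over char-3-gram count profiles (lowercased;
strings shorter than 3 characters get a single padded gram so short gene
symbols keep a non-empty profile), `min_sim = 0.7` by default. The
approximate-search contract is met by inverted-index candidate pruning
(entries sharing at least one gram — exactly the entries with non-zero
cosine), so recall against exhaustive search is exact by construction;
tests verify the equality on generated dictionaries. Proteins link against
the gene namespace and receive the encoding gene's identifier.

Decision rules ship as a registry of generic filters (link-probability
threshold, unlinked-node drop, type whitelist, degree cap) applied in
configured order, each logging its removals; concrete production rule sets
are deployment-specific, so the framework is configurable rather than
prescriptive. Node merging collapses identifier-sharing nodes
(provenance unioned, merge-induced self-loops dropped, parallel edges
keeping the maximum link probability — max rather than mean is a choice;
the count is recoverable from provenance). Trigger reduction removes
trigger nodes and connects gene/protein neighbours to disease neighbours of
each trigger component. Integration reduces and merges each per-document
graph, then merges across documents by identifier (unlinked nodes collapse
on lowercased surface within their type — a pragmatic fallback that can
over-merge homonyms, documented as such). All three are idempotent where
meaningful and order-independent, with representative node fields chosen by
sort order rather than input order to keep results permutation-invariant.

## Known limitations

- The tiny encoder is a correctness- and procedure-level stand-in for
  pretrained biomedical encoders; absolute scores on real corpora are out
  of scope, and the package asserts only ordinal patterns (DE improves
  recall; onlyRE beats joint) on synthetic data.
- Joint inference enumerates all spans up to the width cap per document;
  at `max_width = 10` this is linear in length but with a constant that
  makes very long documents slow in R.
- Relation types beyond the single symmetric `LinkedOf`, cross-document
  coreference, n-ary relations, and nested-mention decoding are not
  modelled.
- The generator's negatives are easy (no hard confounders such as a
  trigger between an unlinked pair); real-text precision will be
  optimistic relative to it.
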