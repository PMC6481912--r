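---
title: "Context-aware ABC models for literature-based discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware ABC models for literature-based discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcontext)
```

## The problem and the models

Closed literature-based discovery asks: given two entities A and C with a
known or suspected relationship, which intermediate entities B connect
them across the literature? The classical ABC scheme joins any relation
containing A with partner B to any relation containing B with partner C.
When relations come from sentence-level co-occurrence, this produces many
spurious intermediates, because nothing requires the two supporting
relations to describe comparable biology — one may hold in cultured mouse
cells under a drug challenge, the other in human autopsy tissue.

`abcontext` implements three variants of the scheme over a shared
relation-table representation:

* **co-occurrence model** — every unordered pair of distinct gene symbols
  co-mentioned in a sentence is a relation; A–B and B–C relations join
  unconditionally. The permissive baseline.
* **context model** — each relation carries a four-slot *biological
  context* (cell, drug, disease, organism) extracted from its sentence;
  relations with no context are discarded, and an A–B relation joins a
  B–C relation only when their context similarity reaches a threshold.
* **context-assignment model** — the per-abstract union of all extracted
  context elements is first stamped onto every relation of that abstract
  (including those that already had context), recovering the many
  relations whose sentences carry no context of their own, at the cost of
  occasionally widening a context until a previously matching pair of
  relations no longer agrees.

## Context extraction

Context elements are entities of the four context types that occur inside
*conditioning clauses*: prepositional clauses or phrases and
relative-adverb clauses ("... **in** a transgenic mouse model of
TTRVal30Met-related amyloidosis", "... **where** dopaminergic neurons
degenerate"). The original procedure relies on full constituency parsing;
re-implementing a parser is out of scope here, so clause spans are
first-class *input*: any upstream parser (or the bundled corpus
generator) can supply them, and extraction in `mode = "annotated"` uses
them verbatim. A transparent heuristic (`mode = "heuristic"`) is provided
as a fallback: a span opens at a conditioning preposition (*in, within,
under, during, among, from*) or relative adverb (*where, when, while*)
and closes at the next comma, semicolon, period or coordinating
conjunction. The heuristic is deliberately simple and is *measured* on
synthetic data, never asserted to match a parser.

Extracted terms are normalized by lowercasing and whitespace removal
(`"transgenic mouse"` → `"transgenicmouse"`), which is how they key into
the hierarchy vocabularies. A slot may collect several terms from one
sentence (set semantics); unextracted slots are the `NoData` sentinel and
are excluded from similarity computation.

## Context similarity

Each element type has a hierarchy vocabulary in MeSH tree-number style:
terms map to one or more dotted positions such as `C10.228.140.380`, and
the distance between two terms is the minimum edge-path length through
their deepest common dotted prefix. Terms whose positions share no
top-level category are *unrelated* (`Inf`); the original sources never
define a distance across top-level MeSH categories, and mapping
unrelatedness to similarity 0 reproduces the published connect/disconnect
behaviour. A term with several positions takes the minimum distance over
position pairs, the standard reading of a poly-hierarchy.

Per element, similarity is `1 - distance / max_distance`, clamped to
`[0, 1]`. The per-type maximum distances are the published constants —
cell 30, drug 14, disease 26, organism 12 — and are configurable because
generated hierarchies (or newer vocabulary releases) may be deeper;
distances beyond the maximum clamp to similarity 0 rather than erroring.
The aggregate context similarity of two tuples is cosine-style:

$$
\mathrm{sim}(\mathbf{u}, \mathbf{v}) \;=\;
\frac{\sum_{s \in \text{slots shared}} \mathrm{elemsim}(u_s, v_s)}
     {\sqrt{n_1\, n_2}},
$$

where the numerator runs over the slots populated on *both* sides and
`n_i` counts the populated slots of tuple i. The published form of the
denominator is typeset ambiguously; the square-root normalization is the
one consistent with the explicit "modification of cosine similarity"
framing, keeps scores in `[0, 1]`, and reproduces both published worked
values (1.0 for identical single-disease contexts, 0 for unrelated ones).
A second reading — counting only the shared slots in `n_i`, so that
`NoData` slots are excluded from the normalization as well as the
numerator — also reproduces those worked values; it is available as
`normalization = "shared"` but is not validated against any published
number. Set-valued slots score as the maximum over cross pairs and count
once in `n_i`.

Two consequences worth knowing: similarity is symmetric and bounded in
`[0, 1]` (the numerator is at most the number of shared slots, which is
at most `sqrt(n1 n2)`), and it equals 1 exactly when both tuples populate
the same number of slots and every shared slot matches perfectly. The
test suite verifies both exhaustively against a brute-force
reimplementation over a toy vocabulary.

## Path construction and the threshold

`build_paths()` matches endpoints undirectedly on official symbols:
published path listings order entities by position in the A–B–C triple
regardless of which argument slot the entity occupied in the underlying
relation, so voice/direction is metadata, not a constraint. The gate is
*inclusive* (`similarity >= threshold`): the published exact-matching
experiments run at threshold 1 with passing scores of exactly 1.0, which
a strict inequality would make unsatisfiable. Paths are emitted per
supporting relation pair — repeated identical triples with different
provenance appear repeatedly, as in the published listings — and
`dedup_b_entities()` reduces to unique B symbols in first-appearance
order. Negation, voice and relation type never gate connections.

Raising the threshold can only remove connections, so path and B-entity
counts are non-increasing in the threshold; the sweep utilities and tests
rely on this monotonicity.

## Evaluation conventions

Precision is the fraction of deduplicated B entities labelled relevant.
Recall divides by an externally supplied *universe* — in the published
evaluation, the B entities validated under the co-occurrence baseline —
rather than by the intersection with anything the model produced, which
is what makes the low published recall (5 of 45) reproducible. An empty
prediction has precision `NA`, not 0: reporting a zero would fabricate a
score.

## What the synthetic generator states, and what a green test means

`simulate_corpus()` emulates the statistical skeleton of the input
corpus, not its language: template sentences of the form
`"<GENE1> modulates <GENE2> in <term>."` with entity and clause spans
recorded exactly. The stated world is:

* each planted chain contributes one A–B and one B–C sentence, each in
  its own abstract, so per-abstract assignment is controlled;
* matched chains share one identical disease term inside the clause of
  both sentences (similarity exactly 1); mismatched chains draw their two
  terms from unrelated top-level categories (similarity exactly 0);
* a `context_rate` fraction (default 0.3 — contexts are present in a
  minority of sentences, which is the very motivation for assignment) of
  filler sentences carry decoy contexts over a decoy gene pool disjoint
  from all chain endpoints;
* optionally, a `contaminate` fraction of matched chains receive a
  drug-context decoy sentence in their A–B abstract. Per-sentence
  extraction is untouched, but assignment widens the A–B tuple to
  {disease, drug}, dropping its similarity to the B–C tuple to
  $1/\sqrt{2}$ — the documented failure mode in which assignment
  disconnects previously connected relations. Note that a decoy of the
  *same* element type would not disconnect anything, because set-valued
  slots score by their best pair; disconnection requires widening the
  element count.

Because contexts are planted only inside recorded clause spans,
annotated-mode extraction is exact by construction, and the end-to-end
ground-truth tests (100% planted-B recovery at threshold 1) certify the
pipeline's bookkeeping — extraction, assignment, matching, gating,
deduplication — not any linguistic capability. Heuristic-mode behaviour
on real prose, parser quality, named-entity recognition and symbol
dictionaries are all outside what a green suite establishes. Corpus-scale
published counts (tens of thousands of relations over two hundred
thousand abstracts) are likewise out of reach at desk scale and are not
asserted anywhere.

## Numerical and design choices

* Distances are integers; similarities are exact binary fractions only by
  accident, so tests compare with `all.equal` tolerances.
* `UNRELATED` is `Inf`, which flows through `min()`, comparisons and the
  clamp without special cases.
* Symbols and terms are lowercased throughout: published tables mix
  `Apoe`/`apoe` and `Glucose`/`glucose` casing, so case is treated as
  typographic.
* Multi-valued context cells serialize as semicolon-joined sets; the
  published tables only ever print one value per slot, but assignment
  produces genuine sets, and the union (not a cross-product of tuples)
  is what reproduces the published assignment example with one combined
  tuple per abstract.
* Ties and ordering: paths sort by (B, A–B document, B–C document);
  deduplication preserves first appearance. Both are stable under
  re-serialization.
* `build_paths()` applies assignment itself under the
  context-assignment model; assignment is idempotent, so pre-assigned
  input is harmless.
* Whether A–B and B–C must come from disjoint document sets is left
  unenforced: the published worked examples do not enforce it.
* When an abstract's sentences carry contradictory contexts (mouse and
  human, say), assignment unions them; this dilutes similarity by
  construction and is surfaced as the `contaminate` mechanism rather
  than resolved.

## Known limitations

* Verb-based relation extraction is accepted as input (the `Origin`
  column distinguishes it) but never recomputed; only co-occurrence
  extraction is implemented.
* The heuristic clause detector has no notion of syntactic depth and
  will truncate clauses at any comma.
* Cross-element dependencies (a disease implying an organism) are not
  modelled; slots are independent by design.
* Bundled vocabularies are toy stand-ins for MeSH / DrugBank / KEGG with
  plausible tree numbers; real analyses should load real exports via
  `load_hierarchy()`.
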