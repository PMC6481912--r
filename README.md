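# abcontext

Closed-discovery literature mining with biological context, in R.

## The problem

The ABC scheme of literature-based discovery connects two entities A and
C through intermediates B: if some relation links A to B and another
links B to C, the triple A–B–C is a candidate path and B a candidate
mechanism. Built on sentence-level co-occurrence alone, the scheme is
notoriously noisy — nothing stops it joining a relation observed in
cultured mouse cells with one observed in human autopsy tissue.
`abcontext` implements context-aware variants: every relation carries a
four-slot **biological context** (cell, drug, disease, organism)
extracted from conditioning clauses of its sentence, and two relations
join into a path only when their contexts agree.

Context agreement is scored against MeSH-style hierarchy vocabularies.
Per element, similarity is `1 − d/D`, where `d` is the tree distance
between the two terms (edge path through the deepest common dotted
prefix of their tree numbers; unrelated top-level categories score 0)
and `D` a per-type maximum distance (cell 30, drug 14, disease 26,
organism 12). Two context tuples aggregate cosine-style:

    sim(u, v) = Σ_shared elemsim(u_s, v_s) / sqrt(n1 · n2)

with `n_i` the number of populated slots of tuple i and the sum over
slots populated on both sides. An A–B relation connects to a B–C
relation iff `sim ≥ threshold`; threshold 1 demands exact context
matching.

Three models are provided:

| model | relations used | join condition |
|---|---|---|
| `cooccurrence` | all | unconditional |
| `context` | only context-bearing | `sim ≥ threshold` |
| `context_assignment` | all, after per-abstract context union is stamped on every relation of the abstract | `sim ≥ threshold` |

## Worked example

The bundled synthetic relation set reconstructs a published
APOE–MAPT closed-discovery experiment: at threshold 1 the context model
builds 19 exact-match paths that deduplicate to 7 intermediate genes,
5 of which the experts had judged relevant.

```r
library(abcontext)

rel <- read_relation_table(abc_example("apoe_mapt_relations_synthetic.tsv"))
vocabs <- list(
  disease = load_hierarchy(abc_example("mesh_disease_toy.tsv"), "disease"),
  drug    = load_hierarchy(abc_example("drugbank_drug_toy.tsv"), "drug"))

paths <- build_paths(rel, "apoe", "mapt", model = "context",
                     threshold = 1, vocabs = vocabs)
nrow(paths)
#> [1] 19
head(paths[, c("a", "b", "c", "similarity", "ab_drug", "ab_disease")], 4)
#>      a       b    c similarity ab_drug             ab_disease
#> 1 apoe    bche mapt          1 glucose                   <NA>
#> 2 apoe    bche mapt          1 glucose                   <NA>
#> 3 apoe c9orf72 mapt          1    <NA> frontotemporaldementia
#> 4 apoe c9orf72 mapt          1    <NA> frontotemporaldementia

b <- dedup_b_entities(paths)
b
#> [1] "bche"    "c9orf72" "ins"     "mcidas"  "phgdh"   "snca"    "src"

gold <- read_gold_labels(abc_example("apoe_mapt_context_gold.tsv"))
unlist(evaluate_b_entities(b, gold_labels(gold$relevant,
       c(gold$relevant, sprintf("syngene%02d", 1:40)))))
#> n_predicted       n_hit   precision      recall   f_measure
#>   7.0000000   5.0000000   0.7142857   0.1111111   0.1923077
```

Each path row records the supporting A–B and B–C relations with both
context tuples; `similarity` is the gate score. Precision 0.714 means 5
of the 7 deduplicated B genes carry an expert relevance label; recall
0.111 divides the same 5 hits by a 45-gene reference universe (the
assumed-complete relevant set), illustrating the model's high-precision
/ low-recall trade-off.

The same run is scriptable end to end from a plain-text config
(`run_pipeline("pipeline.conf")`) or from the shell:

```sh
Rscript -e 'abcontext::abc_cli()' abc \
  --relations rel.tsv --model context --a apoe --c mapt --threshold 1 \
  --vocab-disease mesh.tsv --vocab-drug drugbank.tsv --out paths.tsv
```

Synthetic corpora with planted chains and known ground truth come from
`simulate_corpus()`; see the vignette
(`vignettes/context-abc-models.Rmd`) for the model's assumptions, the
generator's stated world and the package's design choices.

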