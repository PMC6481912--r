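Package: abcontext
Title: Context-Aware ABC Models for Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-discovery literature mining with biological context.
    Implements the co-occurrence, context-based and context-assignment-based
    ABC models: extraction of four-slot biological contexts (cell, drug,
    disease, organism) from clause-annotated sentences, abstract-level
    context assignment, a hierarchy-distance context similarity measure over
    MeSH-style tree numbers, threshold-gated A-B-C path construction between
    a fixed A and C, deduplication of intermediate B entities, and
    precision/recall evaluation against gold relevance labels. Includes a
    synthetic corpus and hierarchy generator with known ground truth and a
    file-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
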