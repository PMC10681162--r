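Package: spanrel
Title: Joint Span-Based Entity and Relation Extraction for Gene-Disease Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Document-level extraction of gene-disease relations from annotated
    biomedical text. Reads and writes PubAnnotation-style JSON standoff corpora
    over a twelve-type entity schema, augments trigger-mediated relation graphs
    with direct gene-disease edges, and jointly trains a span-based named-entity
    recognition head together with an attention-augmented relation-extraction
    head over a small trainable subword encoder, sharing a single summed loss.
    Includes a seeded synthetic-corpus generator for fully offline testing,
    five-fold cross-validated graph-based evaluation (precision/recall/F1 over
    matched nodes and edges), character-3-gram entity linking against gene and
    disease dictionaries, configurable decision-rule filtering, and construction
    of merged, trigger-reduced, multi-document knowledge graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
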