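Package: chemkgqa
Title: Knowledge-Graph Question Answering over Chemical Species Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-agnostic framework for natural-language question
    answering over an OntoSpecies-style chemistry knowledge graph.
    Generates question/SPARQL training pairs from an ontology by sampling
    schema subgraphs, grounding them against instance data, attaching
    comparative filters, and verbalizing them in interrogative, imperative
    and keyword forms; encodes SPARQL into a sequence-to-sequence-safe
    representation; post-corrects model output with Levenshtein-based copy
    correction, embedding-based relation realignment and triple-pattern
    expansion; executes SELECT queries against an in-memory triple store;
    and scores translations with exact-match accuracy, corpus BLEU and a
    four-way error taxonomy. Ships a deterministic synthetic fixture
    generator so the full pipeline is testable without trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
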