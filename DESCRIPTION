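Package: verbowl
Title: Verbalize OWL 2 Ontology Axioms as English Sentences for Expert Review
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates the logical axioms of an OWL 2 ontology into plain
    English sentences so that subject-matter experts can review ontology
    content without reading description logic. Loads ontologies from RDF/XML,
    Turtle, OWL/XML or OWL functional syntax, lexicalizes entities from their
    rdfs:label annotations (with a deterministic IRI-fragment fallback),
    renders each of 14 supported axiom types through recursive class-expression
    templates, and emits per-axiom records with an OWL Manchester syntax
    rendering. Also implements a three-scale expert-rating protocol (clarity,
    fidelity of the sentence to the axiom, fidelity of the axiom to the
    domain) with rating-sheet generation, per-ontology and per-axiom-type
    summaries, inter-rater percent agreement, and the Spearman rank
    correlation between clarity and domain fidelity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
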