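Package: goac
Title: Consistency Assurance for Literature-Based Gene Ontology Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quality control of literature-based Gene Ontology
    annotations (GOA). Parses OBO ontologies into a queryable DAG, reads
    evidence-grounded annotation corpora in BioC XML layout, and synthesises
    four typed annotation inconsistencies from consistent instances:
    contradictory regulation polarity (A), over-specific term selection (B),
    unsupportive evidence text (C), and erroneous experimental evidence code
    (D). Ships prior-biased and section-rule baselines, a feature-transparent
    lexical consistency classifier, evidence-level and article-level scoring,
    Shannon-entropy uncertainty sampling, and a linguistic test suite with
    Pearson correlation analysis. Seeded generators for a mini ontology and a
    toy corpus make the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
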