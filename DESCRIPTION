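Package: enzcurate
Title: Evidence-Based Review and Reconciliation of Enzyme Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for systematic review of enzyme annotations across
    multiple databases: ontology-closure queries over Gene Ontology style
    DAGs, Enzyme Commission (EC) number parsing and wildcard matching,
    GAF 2.2 ingestion with negation handling, evidence-code confidence
    triage (high/medium/low), cross-source reconciliation with Venn
    overlap accounting, precision/recall/F1 evaluation against gold
    standards, release-diff ledgers, hierarchical gene-group reports, and
    a seeded synthetic-data generator that plants documented annotation
    error modes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
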