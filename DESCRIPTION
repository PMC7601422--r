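Package: fairsheet
Title: Convert Heterogeneous Lab Spreadsheets into a Semantic Substance Data Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative conversion of experimental spreadsheet workbooks
    (nanosafety and chemical-substance assay templates) into a well-defined
    semantic data model, driven by a JSON mapping configuration. Supports
    row-per-substance layouts and hierarchical dose-response effect blocks
    (sub-block grids and value groups), deterministic hash-based record
    identifiers, dictionary-based metadata harmonization with ontology-style
    annotations, and serialization to a native JSON model, ISA-JSON with a
    nanomaterial component/linkage extension, and an experimental N-Triples
    dump. Includes fixture and template tooling: synthetic workbook
    generation in both layout families, template field extraction, and
    skeleton configuration generation, plus a command-line converter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    purrr,
    readxl,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    xml2,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
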