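---
title: "Mapping lab spreadsheets onto a semantic substance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lab spreadsheets onto a semantic substance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairsheet)
```

## The conversion model and its assumptions

`fairsheet` treats spreadsheet-to-database conversion as the execution of
a declarative mapping. The mapping (a JSON document) binds positions in a
workbook to slots of a semantic data model; the engine is a deterministic
interpreter of that mapping. Three assumptions underlie the design:

1. **The layout is stable per template family, not per file.** One
   configuration is written per layout and reused across the many files
   that share it. Configurations are therefore plain, diffable JSON meant
   to live in version control.
2. **Cells are data, not programs.** Formula results are read as cached
   values; no formula evaluation, styling or color semantics are
   interpreted.
3. **The source is authoritative.** Imported values are kept as close to
   the original as possible; harmonization is a separate, minimal,
   post-parse step that always preserves the original text.

The model itself is substance-centric: a substance (identified by names
and a deterministic hash-based UUID) carries compositions — components
with roles such as main constituent, impurity, additive, or, for
nanomaterials, core, coating and functionalisation, plus linkages between
components ("covalently bonded", "embedded", "encapsulated") — and
protocol applications, each owning citation metadata, an ordered dynamic
parameter list and a list of effect records. An effect record is one
measurement: endpoint, a value or interval with qualifiers drawn from
`=, <, <=, >, >=, ~`, an optional uncertainty with its own free-text
qualifier (e.g. `SD`), a unit, and an ordered list of experimental
conditions.

## Data locations and iteration modes

Every mapped datum is described by an Excel Data Location (EDL) with an
iteration mode:

* `ROW_SINGLE` — the primary sheet is walked row by row, one substance
  record per data row; an EDL needs only a column because the row is
  supplied by the iteration. A row index in this mode is a configuration
  error, reported as such.
* `ABSOLUTE_LOCATION` — a fixed `(row, column)` cell; used for
  single-substance workbooks and for reaching header rows.
* `JSON_VALUE` — the value is a literal in the configuration itself
  (units and endpoint names are the typical case); no cell is read and
  sheet/row/column attributes are rejected.

The `DATA_ACCESS` section provides defaults (iteration mode, sheet, row
range), enabling a short syntax in which EDLs omit whatever the defaults
supply; `resolve_edl()` performs the expansion, never overriding an
explicit attribute, and is idempotent. The mode registry is extensible
(`register_iteration_mode()`) so additional strategies can be added
without changing the engine contract.

**Indexing convention.** Rows and columns are 0-based throughout the
dialect, matching programmatic workbook APIs; column letters ("A", "B",
...) are accepted and converted, matching the user's mental model. Logs
and error messages report A1 notation alongside the 0-based indices.
Sheets are addressable by 0-based index or exact name; the name wins when
both are given, because templates are reordered more often than renamed.

## Effect blocks

Dose–response sheets record a full factorial of experimental factors as a
rectangular region. The dialect describes such a region hierarchically:
an `EFFECT_BLOCK` has an origin, a grid of sub-blocks (e.g. one row of
sub-blocks per replicate), and a sub-block size; each sub-block contains
value groups (e.g. one per exposure time); each group lists value-cell
offsets and the parameters that attach conditions to every value:

* `JSON_VALUE` — a fixed literal for the group;
* `COLUMN_HEADER` — the cell in a fixed header row above the value's
  column (typical for concentration series);
* `ROW_HEADER` — the cell in a fixed column on the value's row (typical
  for time labels);
* `SUB_BLOCK_ROW` / `SUB_BLOCK_COL` — the 1-based grid coordinate
  (typical for replicate numbers);
* `ABSOLUTE_LOCATION` — any fixed cell.

Every non-absent value cell yields exactly one effect record, so for a
complete 2-replicate × 2-time × 9-concentration assay the block expands
to 36 measurements; blank or NA-marked cells reduce the count one for
one. This count law is verified in the test suite against a brute-force
cell walker on randomized small geometries (grids up to 3×3, up to 3
groups, up to 10 values, 100 seeds).

## Numerical and degenerate-input choices

* **Type coercion.** Numeric cells stay numeric; date-typed cells become
  ISO-8601 text at workbook read; all other content is trimmed text.
  Text matching a decimal-comma number (e.g. `"3,14"`) is *not*
  converted — silent locale guessing corrupts data — but flagged in the
  problem report.
* **Absence.** Blank cells and the markers `""`, `"n/a"`, `"N/A"`, `"-"`,
  `"–"` (configurable via `NA_MARKERS`) yield absent fields, not empty
  strings, keeping "value not reported" distinguishable.
* **Qualified values.** Text values failing numeric coercion are run
  through a small total grammar: `<3`, `<=3`, `>3`, `>=3`, `~3`, `=3`
  and the interval forms `3-4` / `3–4` (read as `3 ≤ x ≤ 4`). Anything
  else is stored as a text value. A `VALUE` attribute is treated as an
  exact measurement — lower value with qualifier `=` — which is the one
  place a qualifier is supplied implicitly; bounds read through
  `LO_VALUE`/`UP_VALUE` never gain qualifiers silently.
* **Blank-row termination.** Row iteration ends at `ROW_END` when set,
  otherwise after 2 consecutive fully blank rows (configurable), because
  real templates carry trailing free-text notes.
* **Merged cells.** The anchor value is propagated over the covered
  region at read time, since templates label groups with merged headers.
* **Error policy.** Per-record problems are collected and parsing
  continues, so a curator receives a complete defect report per file;
  `strict = TRUE` makes the first problem fatal. Configuration
  validation likewise collects *all* problems in one pass, each with the
  JSON path, the expected kind and the found kind.

## Identifiers

High-level entities carry automatically generated, hash-based UUIDs used
for linking, grouping and merging. The identifier is a name-based
(version-5-style) UUID over a canonical serialization: the entity-class
namespace tag and the NFC-normalized identity fields joined with `"|"`,
hashed with SHA-1. Namespace tags (`SUBSTANCE`, `PA`, `ASSAY`, ...)
prevent cross-entity collisions. The field lists feeding each entity's
hash are a convention of this package: substances hash their name and
owner name; protocol applications hash the owning substance identifier,
the citation title, the guidelines and the parameter list. Grouping into
investigations and assays has no inferable key, so those identifiers are
only ever set explicitly through configuration.

## Harmonization

Dictionary lookup is applied *after* parsing, deliberately: originals are
stored as close to the source as possible and every annotated term keeps
the original spelling verbatim. The lookup key is a minimal
normalization — Unicode NFKC case folding plus removal of whitespace and
the separators `- _ . /` — which collapses the common spelling variants
of, say, a cell-line name without stemming. Full spell checking is *not*
performed unattended; instead, unmatched terms within edit distance 1 of
a dictionary key are listed in the miss report as suggestions for
curator review. An entry may carry more than one vocabulary annotation,
so public and private dictionaries can annotate the same term.
Harmonization is idempotent because canonical terms are required to be
fixed points of their own dictionary.

## Serialization

Native JSON uses a stable lowerCamelCase key vocabulary mirroring the
data-model attribute names; serialization is lossless and deterministic
(identical records give byte-identical output), and reading back is an
exact inverse — the round-trip property is tested on fixtures and
randomized records. The key layout is recognizable to users of
comparable substance-database APIs without claiming wire compatibility
with any of them.

ISA-JSON export emits an investigation/study/assay skeleton: studies
group records by explicit investigation identifier (one default study
otherwise), assays group protocol applications by protocol identity, and
materials carry the component list with roles and linkages — the
nanomaterial extension. The bundled extension schema
(`inst/schema/isa-material-extension.schema.json`) is this package's own
reconstruction of a role-plus-linkage component model and is labelled as
such. An N-Triples dump over a small fixed vocabulary is available and
flagged experimental; a full semantic mapping is out of scope.

The configuration dialect itself is published as a JSON Schema via
`emit_schema()`. Because no JSON-Schema validator package is part of the
package's dependency footprint, a small structural checker for the
schema subset used (`type`, `required`, `properties`, `items`, `enum`,
`additionalProperties`, `oneOf`, `minimum`, `pattern`) ships as
`check_schema()`; the dialect intentionally covers the three first-class
iteration modes and documents further upstream options as gaps.

## The synthetic template generator

`template_spec()` / `generate_fixture()` produce workbooks in the two
layout families the package targets, together with a companion
configuration and the expected records — three mutually consistent
artifacts from one seed:

* **Row layout** emulates row-per-substance physicochemical templates:
  a header row, one substance per row with name, CAS registry number,
  supplier, a measured zeta potential (mV) and pH.
* **Block layout** emulates single-substance dose–response sheets: a
  test-conditions sheet with identity fields, and a results sheet with a
  concentration header (a doubling series from 10 µg/mL), replicate
  sub-blocks and per-time value groups. The default geometry is 2
  replicates × 2 times (24 h, 48 h) × 9 concentrations — a complete
  colony-forming-efficiency experiment of 36 measurements.

Measured values are drawn from a seeded log-normal with a configurable
absent-cell probability, which exercises NA handling and the count law
without making biological claims. What the generator deliberately does
*not* emulate: formula cells, merged-header variability, multi-substance
block sheets, inconsistent hand-edited layouts, and free-text metadata
noise beyond the NA markers. Passing the closure test (`engine(workbook,
companion config) == expected records`) therefore demonstrates the
mapping machinery is correct, not that any particular real-world template
will parse without curator work — that is exactly the work the
configuration dialect exists to encode.

Field extraction (`extract_template_fields()`) uses a simple, documented
heuristic — a text cell is a header when its column contains a numeric
cell below — and skeleton generation binds only the substance name,
flagging every other detected field `TODO:` for the curator, since
automatic binding of arbitrary headers to model entities is not reliably
inferable.

## Problem sizes and limitations

The test suite and the acceptance script use fixture-scale problems
(up to ~6 substances, block grids up to 3×3, 100 randomized geometries,
200 randomized round-trip records); all complete in seconds and are
fully seeded. Known limitations: XLS (pre-2007) input is not supported;
spreadsheet formulas are read as cached values only; the appendix-level
options of the richer upstream mapping dialects (beyond the three
iteration modes) are intentionally unimplemented and documented as
dialect gaps; RDF output is a minimal experimental triple dump; and the
relational-database, web-GUI and search-index layers of a full data
platform are out of scope.
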