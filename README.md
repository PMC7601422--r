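# fairsheet

Convert heterogeneous experimental spreadsheets — nanosafety and
chemical-substance assay templates — into a well-defined semantic data
model, driven by a declarative JSON mapping configuration, and serialize
the result to machine-readable formats.

## The problem

Nanosafety and physicochemical characterization data is overwhelmingly
recorded in custom Excel templates: convenient for the lab, painful for
databases. Layouts vary per laboratory, metadata is free text, and the
same quantity may live in a row, a column, or a block of cells indexed by
time points and concentrations. Making such files FAIR (Findable,
Accessible, Interoperable, Reusable) requires mapping each layout onto a
common semantic model — and that mapping, not terminology lookup, is the
expensive step.

`fairsheet` makes the mapping declarative. A curator writes a JSON
configuration describing *where* each datum lives; the engine executes it
against the workbook and produces substance records.

## The data model

The unit of conversion is the **substance record**: a chemical substance
or nanomaterial identified by names and a deterministic hash-based UUID,
characterized by one or more **compositions** (components with roles —
main constituent, impurity, additive, or core / coating /
functionalisation for nanomaterials — and linkages between components,
e.g. "covalently bonded"). Measurements attach through **protocol
applications** — one event of applying an experimental protocol, with
citation metadata, a dynamic ordered parameter list, and **effect
records**: endpoint, value or interval with qualifiers
(`x = 3`, `x < 3`, `3 < x ≤ 4`, `x ~ 3`), uncertainty with its own
qualifier (e.g. `SD`), unit, and per-measurement experimental conditions
(concentration, exposure time, replicate, ...).

The mapping dialect is built from **Excel Data Locations** (EDLs): small
JSON objects giving the sheet / row / column of one datum under an
iteration mode — `ROW_SINGLE` (one substance per table row; only a column
is needed, the row comes from the iteration), `ABSOLUTE_LOCATION` (fixed
row and column), or `JSON_VALUE` (a literal from the configuration). A
`DATA_ACCESS` section supplies defaults so configurations can use a short
syntax. Dose–response layouts are handled by **effect blocks**: a
rectangular region divided into a grid of sub-blocks (e.g. replicates),
each holding value groups (e.g. time points) whose value cells each
become one effect record, with conditions assembled from row/column
headers and grid coordinates.

## Worked example

A colony-forming-efficiency workbook with 2 replicates × 2 exposure times
× 9 concentrations, generated by the package's own template tooling and
parsed with its companion configuration:

```r
library(fairsheet)

fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 1))
records <- parse_workbook(fx$workbook, fx$config)
records[[1]]
#> <substance record> NM-203 (SUBSTANCE-1f6bce71-35ef-58c8-9779-89769773ecbc)
#>   1 identifier(s), 0 composition(s), 1 protocol application(s), 36 effect(s)

tab <- effects_table(records)
tab[1:4, c("endpoint", "lo_value", "unit", "condition_concentration",
           "condition_time", "condition_replicate")]
#> # A tibble: 4 x 6
#>   endpoint                  lo_value unit  condition_concentration condition_time
#> 1 COLONY FORMING EFFICIENCY     15.6 %                         10             24
#> 2 COLONY FORMING EFFICIENCY     22.9 %                         20             24
#> 3 COLONY FORMING EFFICIENCY     25.3 %                         40             24
#> 4 COLONY FORMING EFFICIENCY     15.7 %                         80             24
```

One `EFFECT_BLOCK` section expanded into 2 × 2 × 9 = 36 effect records,
each carrying its concentration (µg/mL), exposure time (h) and replicate
as conditions. `to_native_json()` serializes the records losslessly
(`from_native_json()` reads them back identically), `to_isa_json()` emits
an ISA-JSON investigation/study/assay skeleton whose materials carry
component roles and linkages, and `harmonize_records()` applies
dictionary lookup (e.g. "BEAS 2B" / "Beas 2B" / "BEAS -2B" → one
canonical cell type) while preserving the original spelling verbatim.

A command-line front end ships as `exec/fairsheet` with subcommands
`convert`, `validate`, `fields`, `skeleton` and `fixture`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","fairsheet",package="fairsheet"))')" \
  convert --input workbook.xlsx --config config.json \
  --format isajson --output out.json
```

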