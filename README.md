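# faangr

Offline engine for FAANG-style metadata standards in farmed- and
companion-animal genomics: versioned, tiered metadata checklists
("rulesets"), ontology-hierarchy-aware validation of animal / specimen /
experiment records, controlled missing-value vocabulary, livestock
crossbreed nomenclature, full-vs-legacy standard classification with
version labelling, spreadsheet/JSON intake with annotated error reports,
and conversion of validated records into BioSamples-style JSON and
ENA-style experiment XML.

It is written for data-coordination and curation teams who need to
validate community submissions against a machine-readable standard
without any network services, and for methodologists who want a testable,
self-contained implementation of the validation semantics.

## The model

A **ruleset** is a versioned checklist. Every field rule carries a
requirement tier — *mandatory*, *recommended* or *optional* — and a value
contract (enum, number + units, ISO date, URI, DOI, or an ontology term
constrained to the descendants of given root terms, e.g. *health status*
⊑ PATO:0000461 (normal) ∪ EFO:0000408 (disease)). Absent values are
expressed with exactly four controlled strings — `not applicable`,
`not collected`, `not provided`, `restricted access` — that interact with
the tiers as a decision table (on a recommended field NA/RA pass while
NC/NP warn; see the methods vignette for the full matrix). Crossbred
animals carry their species' LBO *crossbreed* term plus a name in the
`breed sire × breed dam` grammar, sire first. A record **meets the full
standard** when it validates with zero errors; failing that it may meet a
paired **legacy** standard whose mandatory fields are a subset of the
full ones; records are labelled with the newest ruleset version they
meet.

## Worked example

```r
library(faangr)
rules <- faang_rulesets()   # bundled v3.5 full + legacy standards
graph <- faang_ontology()   # bundled ontology fixture graph

count_fields_by_tier(rules$animal$full)
#>   mandatory recommended    optional
#>          27           7          32

# a seeded submission: 3 animals + specimens + experiments,
# with two controlled defects injected
sub <- generate_submission(
  3, defect_spec(missing_term_on_recommended = 1, legacy_only = 1),
  seed = 42)
report <- validate_submission(sub$records, rules, graph)
report
#> <submission_report> 9 records: 7 pass, 1 pass with warnings, 1 fail

report$reports[[1]]
#> <record_report> ANIMAL0001: pass_with_warnings, standard: full (0 errors, 1 warnings)
subset(report$reports[[1]]$outcomes, status == "warning",
       c(field_name, status, code))
#>   field_name  status                  code
#> 8 birth date warning missing_value_warning

report$reports[[7]]
#> <record_report> ANIMAL0003: fail, standard: legacy (1 errors, 0 warnings)
subset(report$reports[[7]]$outcomes, status == "error",
       c(field_name, status, code))
#>            field_name status                    code
#> 7 developmental stage  error mandatory_field_missing

parse_crossbreed_name("Texel sire x Scottish Blackface dam")
#> <crossbreed> Texel sire × Scottish Blackface dam
```

The first animal supplied `not collected` for a recommended field: the
validator accepts the record but displays a warning asking for the value
if available. The third animal lacks *developmental stage* — mandatory in
the full standard but optional in the legacy one — so it fails the full
standard yet is classified `legacy`. The crossbreed name parses (ASCII
`x` accepted) and re-serializes canonically with the `×` sign.

A command-line wrapper ships at `inst/cli/faangr`
(`validate`, `convert`, `render-rules`, `diff-rules`, `gen-fixtures`).

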