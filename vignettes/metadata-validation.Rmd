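---
title: "Tiered metadata standards and ontology-aware validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered metadata standards and ontology-aware validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faangr)
```

## The problem

Functional-genomics consortia for farmed and companion animals collect
assay data from dozens of laboratories across many species. The value of
those datasets for cross-depositor analysis depends almost entirely on the
quality of the metadata describing each animal, specimen and experiment.
faangr implements the machinery such a consortium needs to police metadata
quality offline: a machine-readable, versioned checklist format
("ruleset"), an ontology-aware validator, controlled vocabulary for missing
data, breed nomenclature checks, classification of records against a full
or a relaxed legacy standard, and converters to the document styles the
EMBL-EBI archives accept.

## Rulesets and requirement tiers

A ruleset is a versioned list of field rules grouped into sections. Each
rule carries one of three requirement tiers:

* **mandatory** — the record must supply a valid value;
* **recommended** — important for downstream analysis but not attainable by
  every depositor; absence is a warning, never an error;
* **optional** — freely omitted.

The intermediate *recommended* tier is the load-bearing design feature: it
lets the standard demand fields such as *birth date* prominently without
excluding otherwise sound submissions that cannot provide them.

The bundled replica standards (version 3.5) reproduce the published tier
distribution — 27/7/32 mandatory/recommended/optional fields for animals
and samples, 35/14/3 for experimental assays — and all published example
fields (*sex*, *organism*, *breed*, *developmental stage*, *birth date*,
*health status*, *publication*, *birth location*, *specimen volume*,
*assay type*, *extraction protocol*, *experiment target*, *sequencing
date*, *sequencing location*, *restriction enzyme*, *sample storage*,
*library selection*). The remaining slots carry plausibly named fields of
realistic types; the replica reproduces the documented structure, not the
field-for-field content of the real release. Rule order is significant and
preserved, so `render_ruleset_table()` output is reproducible.

Sections may carry an applicability condition — a single
attribute-equals-value predicate (e.g. *assay type* = `"RRBS"`). Rules in
non-applicable sections produce no outcomes. The bundled rulesets
deliberately use unconditional sections only: the replica's headline
property is that an empty animal record draws exactly one error per
mandatory rule, and conditional sections would make that count depend on
the record. Conditional grouping is exercised by synthetic rulesets in the
test suite instead.

One ruleset covers animals *and* specimens (the published tier counts are
for "animals and samples" as a unit), so a ruleset with
`record_domain = "animal"` accepts records of domain `animal` or
`specimen`; `experiment` rulesets accept experiment records only.

## Missing values

Exactly four controlled strings stand in for absent values: `not
applicable`, `not collected`, `not provided` and `restricted access`.
The standard's stated semantics cover the recommended tier: *not
applicable* and *restricted access* pass, *not collected* and *not
provided* warn. The interaction with the other tiers is this package's
own documented extension, chosen to be consistent with the stated row:

| tier        | concrete valid value | not applicable | not collected | not provided | restricted access | absent  |
|-------------|----------------------|----------------|---------------|--------------|-------------------|---------|
| mandatory   | pass                 | error          | error         | error        | **warning**       | error   |
| recommended | pass                 | pass           | warning       | warning      | pass              | warning |
| optional    | pass                 | info           | info          | info         | info              | silent  |

*Restricted access* on a mandatory field is a warning, not an error,
because the value exists — it is merely withheld. Constraint checks (enum
membership, units, dates, ontology descent) run only on concrete values;
a missing-value term never triggers them.

## Ontology constraints

Hierarchy rules are phrased as descendant constraints: a field constrained
to root terms accepts any term reachable from the supplied term via is-a
edges. Only is-a edges are modelled (the rules never need part-of), the
graph may be a DAG (multiple parents), and IRI, underscore and CURIE
spellings all normalize to `PREFIX:LOCAL`. Whether the constraint root
itself is acceptable is not specified by the standard; it is exposed as the
per-constraint `include_root` flag, defaulting to `TRUE`, and use of the
root is flagged in the report (`ontology_root_term_used`) so curators can
ask for something more specific.

Free-text matching (`match_term_label()`) is a local, deterministic
approximation of remote curation services: exact label matches rank above
synonym matches above case/punctuation-normalized matches, with
lexicographic CURIE order breaking ties. It consults only the loaded
graph; no network service is involved.

Ancestor closures are computed once at graph construction, so descendant
queries are O(1) lookups afterwards; the suite checks them against a
brute-force boolean-matrix transitive closure on random DAGs.

## Breeds and crossbreeds

Breed names resist global standardisation, so records carry both the
submitter's preferred display name and a Livestock Breed Ontology term id.
Crossbred animals use the species-specific *crossbreed* term
(LBO:0001036 for cattle, LBO:0001038 for goat) plus a custom name in the
grammar

```
cross  := parent " sire × " parent " dam"
parent := breed-name | "(" cross ")" | "unknown"
```

with the sire always first. The full published guidance for unknown and
crossbred parents lives on a wiki that prints only the base format, so the
recursive part of this grammar is a reconstruction: crossbred parents are
parenthesised, an unknown parent is the literal token `unknown`, and both
the multiplication sign and a plain ASCII `x` are accepted on input while
canonical serialization always uses `×`. Parse errors report a position or
reason; a name containing the sire/dam markers must parse (a purebred name
never contains them).

## Standards classification and versioning

A record meets the **full** standard when it validates with zero errors
under the full ruleset; otherwise it meets **legacy** when the paired
legacy ruleset (a minimal mandatory core — material and organism for
samples, assay type and experiment target for experiments — with the
remainder optional) yields zero errors; otherwise **none**. Loading a
legacy ruleset with its declared full pair enforces the subset invariant
(legacy mandatory ⊆ full mandatory), which makes classification monotone:
full implies legacy.

Versions are dotted `major.minor` numerals compared numerically.
`label_version()` returns the newest release a record still meets, so
records archived under an older release remain honestly labelled;
`diff_rulesets()` reports added, removed, tier-changed and
constraint-changed fields between releases.

## Records on disk

Spreadsheet templates use a single header row derived from the ruleset:
ontology fields expand to `<field>` / `<field> Term Source REF` /
`<field> Term Source ID` triplets (the de facto archive convention) and
unit-bearing fields add `<field> Unit`; four bookkeeping columns carry the
record id, domain and the `derived_from` / `child_of` links. The expansion
is invertible, so spreadsheet and JSON intake yield equal records for
equal content. Tab-separated text is the canonical template format — it
survives version control, diffing and byte-identity checks — and `.xlsx`
workbooks are accepted on the read side; annotated copies (original cells
plus `Validation status` and `Validation messages` columns, which readers
ignore on resubmission) are emitted as TSV. Registration details
(contributors and their EFO:0002012 role terms) travel in the JSON form
only; the spreadsheet layout has no registration columns.

Dates are ISO 8601 with the format recorded as a unit string
(`YYYY-MM-DD`, `YYYY-MM`, `YYYY`), which lets partial dates pass cleanly.
All files are UTF-8; the `×` sign must and does survive spreadsheet round
trips.

Converters emit BioSamples-style JSON (characteristics with expanded IRIs
and `derived from` / `child of` relationships) and a minimal ENA-style
`EXPERIMENT_SET` XML with TAG/VALUE/UNITS attribute triples, validated
against a schema shipped with the package. The ENA dialect is deliberately
minimal: archive-side fields such as accessions cannot exist before
submission. Converters never re-validate and never invent values — the
(field, value) multiset is preserved exactly.

## The synthetic submission generator

`generate_submission()` produces the study conditions the engine is tested
under: `n` animals, each with one derived specimen and one experiment
(3·n records), every record valid by construction except for requested
injected defects, each of which has a hand-derivable expected outcome
(overall status, standard met, error codes). Defaults chosen once:
roughly one animal in five is a crossbred cattle/goat exercising the
nomenclature rules, a quarter of animals carry `child_of` pedigree links,
optional fields appear with probability 0.2, and one animal in ten carries
an off-checklist field exercising additional-field pass-through. The
generator is seeded and restores the caller's RNG state; identical seeds
give byte-identical output files.

What it emulates is *structural* realism only: field coverage, tier
interactions, link topology, defect classes. It does not emulate
real-world value distributions, free-text noise, multi-species breed
mismatches or partially overlapping submissions — so green end-to-end
tests demonstrate that the engine's decision table, hierarchy checks and
bookkeeping are correct, not that real submissions are this tidy.

Problem sizes used by the test suite and the acceptance script — a
1002-record grid with 15 records per defect class, 100 random DAGs of up
to 200 terms, 50 ruleset extensions, depth-4 breed trees — were chosen as
comfortable desk-scale checks of the properties involved; all are
parameters, not limits.

## Numerical and degenerate-input choices

* Field-name matching is case-insensitive after whitespace normalization
  (spreadsheet headers vary); enum values and units match exactly.
* Unknown ontology terms on *additional* (off-checklist) fields warn
  rather than error: the standard does not govern those fields.
* A crossbreed name for a species with no registered crossbreed term
  warns (`crossbreed_term_unmapped_species`) instead of erroring; the map
  ships with the two published species and is user-extensible.
* Validation of one record is pure and deterministic: identical inputs
  give byte-identical reports.
* Error codes are stable snake_case identifiers; messages are for humans,
  codes for machines.

## Known limitations

* No OWL reasoning; is-a closure only.
* The free-text matcher has no curation memory; it is a ranking over the
  loaded graph's labels and synonyms.
* The ENA XML dialect and the template layout are minimal conventions,
  not the archives' full schemas.
* Legacy classification assumes a declared full/legacy pairing; unpaired
  legacy rulesets are loadable but unchecked against the subset
  invariant.
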