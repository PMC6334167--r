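#' Build the bundled fixture ontology
#'
#' A deterministic mini ontology graph carrying the anchor terms the
#' standard's hierarchy rules cite — PATO:0000461 (normal), EFO:0000408
#' (disease), EFO:0002012 (organization role, the contributor-role root),
#' LBO:0001036 (cattle crossbreed) and LBO:0001038 (goat crossbreed) —
#' together with synthetic descendants under each anchor, purebred
#' Livestock Breed Ontology leaves, sex and developmental-stage terms,
#' species taxa and anatomical parts.  Synthetic filler terms use the
#' reserved `FXT:` prefix so they can never shadow real CURIEs; breed
#' leaves use the `LBO:` prefix with a clearly synthetic 9000000+ range
#' because breed validation requires LBO terms.
#'
#' @return An [ontology_graph()]; repeated calls give identical graphs.
#' @export
build_fixture_ontology <- function() {
  t <- function(id, label, parents = character(0), synonyms = character(0)) {
    list(id = id, label = label, parents = parents, synonyms = synonyms)
  }
  terms <- list(
    # quality / health status branch
    t("PATO:0000001", "quality"),
    t("PATO:0000461", "normal", "PATO:0000001", c("healthy state")),
    t("FXT:0000101", "healthy", "PATO:0000461"),
    t("FXT:0000102", "clinically healthy", "PATO:0000461"),
    t("FXT:0000103", "specific pathogen free", "PATO:0000461"),
    t("FXT:0000104", "vaccinated healthy", "PATO:0000461"),
    t("FXT:0000105", "recovered", "PATO:0000461"),
    t("EFO:0000408", "disease", character(0), c("disorder")),
    t("FXT:0000201", "mastitis", "EFO:0000408"),
    t("FXT:0000202", "foot rot", "EFO:0000408"),
    t("FXT:0000203", "avian influenza", "EFO:0000408"),
    t("FXT:0000204", "bovine tuberculosis", "EFO:0000408"),
    t("FXT:0000205", "lameness", "EFO:0000408"),
    t("FXT:0000206", "respiratory disease", "EFO:0000408",
      c("disease of respiratory system")),
    # contributor roles
    t("EFO:0002012", "organization role", character(0), c("contributor role")),
    t("FXT:0000301", "submitter", "EFO:0002012"),
    t("FXT:0000302", "data analyst", "EFO:0002012"),
    t("FXT:0000303", "experiment performer", "EFO:0002012"),
    t("FXT:0000304", "biomaterial provider", "EFO:0002012"),
    t("FXT:0000305", "funder", "EFO:0002012"),
    # sex
    t("PATO:0000047", "biological sex", "PATO:0000001", c("sex")),
    t("PATO:0000384", "male", "PATO:0000047"),
    t("PATO:0000383", "female", "PATO:0000047"),
    # developmental stage
    t("EFO:0000399", "developmental stage", character(0), c("life stage")),
    t("FXT:0000401", "adult", "EFO:0000399"),
    t("FXT:0000402", "juvenile", "EFO:0000399"),
    t("FXT:0000403", "neonate", "EFO:0000399"),
    t("FXT:0000404", "embryo", "EFO:0000399"),
    t("FXT:0000405", "fetal stage", "EFO:0000399"),
    # taxa
    t("NCBITaxon:1", "organism"),
    t("NCBITaxon:9913", "Bos taurus", "NCBITaxon:1", c("cattle", "cow")),
    t("NCBITaxon:9925", "Capra hircus", "NCBITaxon:1", c("goat")),
    t("NCBITaxon:9940", "Ovis aries", "NCBITaxon:1", c("sheep")),
    t("NCBITaxon:9823", "Sus scrofa", "NCBITaxon:1", c("pig")),
    t("NCBITaxon:89462", "Bubalus bubalis", "NCBITaxon:1",
      c("water buffalo")),
    # livestock breeds
    t("LBO:0000000", "livestock breed", character(0), c("breed")),
    t("LBO:0001036", "cattle crossbreed", "LBO:0000000", c("cattle cross")),
    t("LBO:0001038", "goat crossbreed", "LBO:0000000", c("goat cross")),
    t("LBO:9000001", "Angus", "LBO:0000000", c("Aberdeen Angus")),
    t("LBO:9000002", "Hereford", "LBO:0000000"),
    t("LBO:9000003", "Holstein", "LBO:0000000"),
    t("LBO:9000004", "Texel", "LBO:0000000"),
    t("LBO:9000005", "Scottish Blackface", "LBO:0000000"),
    t("LBO:9000006", "Suffolk", "LBO:0000000"),
    t("LBO:9000007", "Boer", "LBO:0000000"),
    t("LBO:9000008", "Saanen", "LBO:0000000"),
    t("LBO:9000009", "Duroc", "LBO:0000000"),
    t("LBO:9000010", "Landrace", "LBO:0000000"),
    t("LBO:9000011", "Large White", "LBO:0000000"),
    t("LBO:9000012", "Mediterranean", "LBO:0000000"),
    t("LBO:9000013", "Pandharpuri", "LBO:0000000"),
    t("LBO:9000014", "Jafarabadi", "LBO:0000000"),
    t("LBO:9000015", "Bhadawari", "LBO:0000000"),
    # anatomy
    t("UBERON:0001062", "anatomical entity"),
    t("FXT:0000501", "liver", "UBERON:0001062"),
    t("FXT:0000502", "muscle tissue", "UBERON:0001062"),
    t("FXT:0000503", "blood", "UBERON:0001062"),
    t("FXT:0000504", "skin", "UBERON:0001062"),
    t("FXT:0000505", "brain", "UBERON:0001062"),
    # molecular targets for experiments
    t("FXT:0000300", "molecular target"),
    t("FXT:0000311", "polyA RNA", "FXT:0000300"),
    t("FXT:0000312", "total RNA", "FXT:0000300"),
    t("FXT:0000313", "open chromatin", "FXT:0000300"),
    t("FXT:0000314", "H3K4me3", "FXT:0000300"),
    t("FXT:0000315", "H3K27ac", "FXT:0000300"),
    t("FXT:0000316", "DNA methylation", "FXT:0000300"),
    t("FXT:0000317", "input DNA", "FXT:0000300")
  )
  ontology_graph(terms)
}

# all proper descendants of root present in the graph
.descendants_of <- function(graph, root) {
  root <- normalize_curie(root)
  ids <- names(graph$terms)
  ids[vapply(ids, function(id) id != root &&
               root %in% term_ancestors(graph, id), logical(1))]
}

.r <- function(name, tier, type = "text", ...) {
  field_rule(name, tier, type, ...)
}

.animal_full_rules <- function() {
  oc <- function(root, include_root = FALSE) list(list(root = root,
                                                       include_root = include_root))
  list(
    standard = list(
      .r("material", "mandatory", "enum",
         allowed_values = c("organism", "specimen from organism")),
      .r("project", "mandatory", "enum", allowed_values = "FAANG"),
      .r("availability", "optional", "uri"),
      .r("same as", "optional"),
      .r("secondary project", "optional")
    ),
    animal = list(
      .r("organism", "mandatory", "ontology_id",
         ontology_constraints = oc("NCBITaxon:1")),
      .r("sex", "mandatory", "ontology_id",
         ontology_constraints = oc("PATO:0000047")),
      .r("breed", "mandatory", "ontology_id",
         ontology_constraints = oc("LBO:0000000")),
      .r("developmental stage", "mandatory", "ontology_id",
         ontology_constraints = oc("EFO:0000399")),
      .r("birth date", "recommended", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      field_rule("health status", "recommended", "ontology_id",
                 ontology_constraints = list(
                   list(root = "PATO:0000461", include_root = TRUE),
                   list(root = "EFO:0000408", include_root = TRUE)),
                 allow_multiple = TRUE),
      .r("publication", "recommended", "doi"),
      .r("birth weight", "recommended", "number",
         valid_units = c("kilograms", "grams")),
      .r("placental weight", "recommended", "number",
         valid_units = c("kilograms", "grams")),
      .r("delivery ease", "recommended", "enum",
         allowed_values = c("normal autonomous delivery", "c-section",
                            "veterinarian assisted")),
      .r("delivery timing", "recommended", "enum",
         allowed_values = c("early parturition", "full-term parturition",
                            "delayed parturition")),
      .r("birth location", "optional"),
      .r("birth location latitude", "optional", "number",
         valid_units = "decimal degrees"),
      .r("birth location longitude", "optional", "number",
         valid_units = "decimal degrees"),
      .r("pedigree", "optional", "uri"),
      .r("sire id", "optional"),
      .r("dam id", "optional"),
      .r("diet", "optional"),
      .r("environmental conditions", "optional")
    ),
    specimen = list(
      .r("specimen collection date", "mandatory", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      .r("animal age at collection", "mandatory", "number",
         valid_units = c("days", "weeks", "months", "years")),
      .r("specimen collection protocol", "mandatory", "uri"),
      .r("sampling to preparation interval", "mandatory", "number",
         valid_units = c("minutes", "hours", "days")),
      .r("specimen collection method", "mandatory"),
      .r("organism part", "mandatory", "ontology_id",
         ontology_constraints = oc("UBERON:0001062")),
      .r("specimen collector", "mandatory"),
      .r("animal welfare compliance", "mandatory"),
      .r("ethics approval number", "mandatory"),
      .r("specimen preservation method", "mandatory", "enum",
         allowed_values = c("frozen", "paraffin block", "RNAlater", "fresh")),
      .r("specimen storage temperature", "mandatory", "number",
         valid_units = "degrees celsius"),
      .r("number of pieces", "mandatory", "number", valid_units = "count"),
      .r("geographic location", "mandatory"),
      .r("supplier", "mandatory"),
      .r("sample processing laboratory", "mandatory"),
      .r("collection site", "mandatory"),
      .r("storage facility", "mandatory"),
      .r("transport conditions", "mandatory"),
      .r("specimen handling protocol", "mandatory", "uri"),
      .r("date of preservation", "mandatory", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      .r("preservation protocol", "mandatory", "uri"),
      .r("specimen volume", "optional", "number",
         valid_units = c("millilitres", "microlitres")),
      .r("specimen size", "optional", "number",
         valid_units = c("square centimetres", "cubic centimetres")),
      .r("specimen weight", "optional", "number",
         valid_units = c("grams", "kilograms")),
      .r("specimen picture url", "optional", "uri"),
      .r("gestational age at sample collection", "optional", "number",
         valid_units = c("days", "weeks")),
      .r("average incubation temperature", "optional", "number",
         valid_units = "degrees celsius"),
      .r("average incubation humidity", "optional", "number",
         valid_units = "percent"),
      .r("embryonic stage", "optional"),
      .r("fasted status", "optional", "enum",
         allowed_values = c("fed", "fasted", "unknown")),
      .r("cell type", "optional"),
      .r("physiological stage", "optional"),
      .r("lactation stage", "optional"),
      .r("reproductive condition", "optional"),
      .r("treatment", "optional"),
      .r("housing condition", "optional"),
      .r("bedding material", "optional"),
      .r("feed supplier", "optional"),
      .r("water source", "optional"),
      .r("transport duration", "optional", "number",
         valid_units = c("minutes", "hours")),
      .r("specimen purchase date", "optional", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      .r("notes", "optional")
    )
  )
}

.experiment_full_rules <- function() {
  list(
    `experiment standard` = list(
      .r("assay type", "mandatory", "enum",
         allowed_values = c("RNA-seq", "ChIP-seq", "ATAC-seq", "WGS",
                            "RRBS", "WGBS", "Hi-C", "CAGE-seq",
                            "DNase-seq")),
      .r("experiment target", "mandatory", "ontology_id",
         ontology_constraints = list(list(root = "FXT:0000300",
                                          include_root = FALSE))),
      .r("extraction protocol", "mandatory", "uri"),
      .r("experiment description", "mandatory"),
      .r("biological replicate number", "mandatory", "number",
         valid_units = "count"),
      .r("technical replicate number", "mandatory", "number",
         valid_units = "count"),
      .r("input material quantity", "mandatory", "number",
         valid_units = c("nanograms", "micrograms")),
      .r("experimental protocol", "mandatory", "uri"),
      .r("data processing protocol", "mandatory", "uri"),
      .r("reference genome", "mandatory"),
      .r("checksum method", "mandatory", "enum",
         allowed_values = c("md5", "sha256")),
      .r("file format", "mandatory", "enum",
         allowed_values = c("fastq", "bam", "cram")),
      .r("publication", "recommended", "doi"),
      .r("experiment performer", "recommended"),
      .r("protocol deviation", "recommended"),
      .r("sample storage", "optional", "enum",
         allowed_values = c("frozen -80", "frozen -20", "liquid nitrogen",
                            "ambient")),
      .r("sample storage processing", "optional")
    ),
    library = list(
      .r("library preparation protocol", "mandatory", "uri"),
      .r("library preparation date", "mandatory", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      .r("library preparation location", "mandatory"),
      .r("library preparation kit", "mandatory"),
      .r("library name", "mandatory"),
      .r("paired end", "mandatory", "enum",
         allowed_values = c("single", "paired")),
      .r("read length", "mandatory", "number", valid_units = "bases"),
      .r("insert size", "mandatory", "number", valid_units = "bases"),
      .r("number of pcr cycles", "mandatory", "number",
         valid_units = "count"),
      .r("fragmentation method", "mandatory", "enum",
         allowed_values = c("sonication", "enzymatic", "tagmentation",
                            "none")),
      .r("size selection method", "mandatory"),
      .r("quality control method", "mandatory"),
      .r("nucleic acid concentration", "mandatory", "number",
         valid_units = "nanograms per microlitre"),
      .r("purity ratio 260 280", "mandatory", "number"),
      .r("rna integrity number", "mandatory", "number"),
      .r("adapter sequence", "mandatory"),
      .r("multiplexing barcode", "mandatory"),
      .r("library preparation location latitude", "recommended", "number",
         valid_units = "decimal degrees"),
      .r("library preparation location longitude", "recommended", "number",
         valid_units = "decimal degrees"),
      .r("restriction enzyme", "recommended"),
      .r("fragment size distribution", "recommended"),
      .r("spike-in control", "recommended"),
      .r("library selection", "optional", "enum",
         allowed_values = c("polyA", "random", "size-fractionated",
                            "MNase", "restriction digest"))
    ),
    sequencing = list(
      .r("sequencing platform", "mandatory", "enum",
         allowed_values = c("Illumina HiSeq 2500", "Illumina NovaSeq 6000",
                            "Illumina MiSeq", "PacBio Sequel",
                            "Oxford Nanopore PromethION")),
      .r("sequencing kit", "mandatory"),
      .r("flowcell type", "mandatory"),
      .r("base calling software", "mandatory"),
      .r("demultiplexing software", "mandatory"),
      .r("run center", "mandatory"),
      .r("sequencing date", "recommended", "date",
         valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY")),
      .r("sequencing location", "recommended"),
      .r("sequencing location latitude", "recommended", "number",
         valid_units = "decimal degrees"),
      .r("sequencing location longitude", "recommended", "number",
         valid_units = "decimal degrees"),
      .r("sequencing coverage target", "recommended", "number",
         valid_units = "fold"),
      .r("duplicate rate estimate", "recommended", "number",
         valid_units = "percent")
    )
  )
}

.as_legacy <- function(full, keep_mandatory) {
  sections <- lapply(full$sections, function(s) {
    rules <- lapply(s$rules, function(r) {
      if (!tolower(r$name) %in% tolower(keep_mandatory)) {
        r$requirement <- "optional"
      }
      r
    })
    rule_section(s$name, rules = rules, condition = s$condition)
  })
  ruleset(paste(full$name, "(legacy)"), full$version, "legacy",
          full$record_domain, sections)
}

#' Build the bundled replica rulesets
#'
#' Constructs the four standards shipped with the package: the full
#' animals-and-samples and experiment rulesets at version 3.5 — whose tier
#' distributions match the published standard (27 mandatory / 7 recommended
#' / 32 optional fields for animals and samples; 35 / 14 / 3 for
#' experimental assays) — and their legacy counterparts, which keep a
#' minimal set of required fields (material and organism; assay type and
#' experiment target) with the remainder optional.  The replica reproduces
#' the documented tier structure and published field examples; remaining
#' fields carry plausible names rather than claiming field-for-field
#' fidelity to the real release.
#'
#' @return Named list of [ruleset()]s: `animal_full`, `animal_legacy`,
#'   `experiment_full`, `experiment_legacy`.
#' @export
build_replica_rulesets <- function() {
  animal_full <- ruleset(
    "FAANG animals and samples", "3.5", "full", "animal",
    sections = mapply(function(name, rules) rule_section(name, rules),
                      names(.animal_full_rules()), .animal_full_rules(),
                      SIMPLIFY = FALSE))
  experiment_full <- ruleset(
    "FAANG experiments", "3.5", "full", "experiment",
    sections = mapply(function(name, rules) rule_section(name, rules),
                      names(.experiment_full_rules()),
                      .experiment_full_rules(), SIMPLIFY = FALSE))
  stopifnot(identical(unname(count_fields_by_tier(animal_full)),
                      c(27L, 7L, 32L)),
            identical(unname(count_fields_by_tier(experiment_full)),
                      c(35L, 14L, 3L)))
  list(
    animal_full = animal_full,
    animal_legacy = .as_legacy(animal_full, c("material", "organism")),
    experiment_full = experiment_full,
    experiment_legacy = .as_legacy(experiment_full,
                                   c("assay type", "experiment target"))
  )
}

#' Load the bundled standards and ontology
#'
#' `faang_rulesets()` loads the four bundled `.ruleset.json` fixtures
#' (checking each legacy ruleset against its full pair) and returns them
#' keyed by domain as [validate_submission()] expects; `faang_ontology()`
#' loads the bundled ontology graph fixture.
#'
#' @return For `faang_rulesets()`: list with `animal` and `experiment`
#'   entries, each `list(full =, legacy =)`.  For `faang_ontology()`: an
#'   [ontology_graph()].
#' @export
faang_rulesets <- function() {
  p <- function(f) system.file("extdata", f, package = "faangr",
                               mustWork = TRUE)
  animal_full <- load_ruleset(p("faang_animal_full.ruleset.json"))
  experiment_full <- load_ruleset(p("faang_experiment_full.ruleset.json"))
  list(
    animal = list(
      full = animal_full,
      legacy = load_ruleset(p("faang_animal_legacy.ruleset.json"),
                            paired_full = animal_full)),
    experiment = list(
      full = experiment_full,
      legacy = load_ruleset(p("faang_experiment_legacy.ruleset.json"),
                            paired_full = experiment_full))
  )
}

#' @rdname faang_rulesets
#' @export
faang_ontology <- function() {
  load_ontology(system.file("extdata", "faang_ontology.graph.json",
                            package = "faangr", mustWork = TRUE))
}

DEFECT_KINDS <- c("drop_mandatory", "missing_term_on_mandatory",
                  "missing_term_on_recommended", "bad_ontology_term",
                  "bad_enum", "bad_units", "malformed_crossbreed",
                  "dangling_link", "legacy_only")

#' Specify defects to inject into a generated submission
#'
#' Each count asks for that many records carrying one controlled defect,
#' with a known expected validation outcome:
#' * `drop_mandatory` — a legacy-required mandatory field removed
#'   (fails both standards),
#' * `missing_term_on_mandatory` — a full-only mandatory field supplied as
#'   `"not provided"` (fails full, meets legacy),
#' * `missing_term_on_recommended` — a recommended field supplied as
#'   `"not collected"` (warning only),
#' * `bad_ontology_term` — a hierarchy-constrained field with a term
#'   outside the constraint roots,
#' * `bad_enum` — a disallowed enumeration value,
#' * `bad_units` — units outside the permitted list,
#' * `malformed_crossbreed` — a crossbreed name violating the grammar,
#' * `dangling_link` — a specimen deriving from a missing record
#'   (link error; the record itself still meets the standard),
#' * `legacy_only` — a full-only mandatory field dropped (meets legacy).
#'
#' @param ... Named counts from the kinds above.
#' @return Named integer vector of class `defect_spec`.
#' @export
defect_spec <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  bad <- setdiff(names(counts), DEFECT_KINDS)
  if (length(bad)) {
    stop("unknown defect kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("defect counts must be non-negative",
                            call. = FALSE)
  out <- stats::setNames(integer(length(DEFECT_KINDS)), DEFECT_KINDS)
  out[names(counts)] <- as.integer(counts)
  structure(out, class = c("defect_spec", "integer"))
}

.pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

# generate one valid attribute for a rule
.gen_attr <- function(rule, graph, desc) {
  name <- rule$name
  units <- if (length(rule$valid_units)) .pick(rule$valid_units)
           else NA_character_
  switch(rule$value_type,
    enum = record_attribute(name, .pick(rule$allowed_values)),
    number = record_attribute(name, as.character(sample.int(500L, 1L)),
                              units = units),
    date = {
      fmt <- if (is.na(units)) "YYYY-MM-DD" else units
      d <- sprintf("%d-%02d-%02d", sample(2010:2017, 1L),
                   sample.int(12L, 1L), sample.int(28L, 1L))
      v <- switch(fmt, "YYYY-MM-DD" = d, "YYYY-MM" = substr(d, 1, 7),
                  "YYYY" = substr(d, 1, 4))
      record_attribute(name, v, units = fmt)
    },
    uri = record_attribute(name,
                           paste0("https://example.org/protocols/",
                                  gsub(" ", "-", name), "-",
                                  sample.int(99L, 1L))),
    doi = record_attribute(name, paste0("10.5281/fxt.",
                                        sample.int(99999L, 1L))),
    ontology_id = {
      roots <- vapply(rule$ontology_constraints, `[[`, character(1), "root")
      pool <- unique(unlist(lapply(roots, function(r) desc[[r]])))
      if (identical(.field_key(name), "breed")) {
        pool <- setdiff(pool, c("LBO:0001036", "LBO:0001038"))
      }
      id <- .pick(pool)
      record_attribute(name, graph$terms[[id]]$label, term_id = id)
    },
    record_attribute(name, paste0(name, " ", sample.int(999L, 1L)))
  )
}

# a fully valid record for a ruleset: every mandatory and recommended rule
# filled; optional rules filled with probability p_optional
.gen_record <- function(id, domain, ruleset, graph, desc,
                        p_optional = 0.2) {
  attrs <- list()
  for (rule in ruleset_rules(ruleset)) {
    fill <- switch(rule$requirement,
                   mandatory = TRUE, recommended = TRUE,
                   optional = stats::runif(1) < p_optional)
    if (fill) attrs[[length(attrs) + 1L]] <- .gen_attr(rule, graph, desc)
  }
  metadata_record(id, domain, attributes = attrs)
}

# replace (in place, preserving position), or drop when attr is NULL
.replace_attr <- function(record, field, attr) {
  key <- .field_key(field)
  keys <- vapply(record$attributes, function(a) .field_key(a$field_name),
                 character(1))
  idx <- which(keys == key)
  if (is.null(attr)) {
    if (length(idx)) record$attributes <- record$attributes[-idx]
  } else if (length(idx)) {
    record$attributes[[idx[1]]] <- attr
    if (length(idx) > 1L) record$attributes <- record$attributes[-idx[-1]]
  } else {
    record$attributes <- c(record$attributes, list(attr))
  }
  record
}

#' Generate a labelled synthetic submission
#'
#' Produces a seeded, reproducible submission of `n` animals, each with one
#' derived specimen and one experiment on that specimen (3n records),
#' validated-by-construction except for the requested injected defects.
#' The expected validation outcome of every record — overall status,
#' standard met and error codes — is recorded alongside, derived from the
#' injected defects alone, so the validator can be checked against the
#' generator end to end.  About one crossbred cattle/goat animal in five
#' exercises the crossbreed nomenclature; occasional extra fields exercise
#' additional-field pass-through.
#'
#' @param n Number of animals; must be at least the total defect count.
#' @param defects A [defect_spec()].
#' @param rulesets Ruleset pairs as returned by [faang_rulesets()].
#' @param graph An [ontology_graph()] (default: the bundled fixture graph).
#' @param seed Integer seed; identical seeds give identical submissions.
#' @param with_contributors Attach a contributor with a valid role term to
#'   each animal?  (Spreadsheet templates do not carry registration
#'   columns, so cross-format round-trip tests disable this.)
#' @return A list of class `labeled_submission`: `records`, `expected`
#'   (data.frame with `id`, `overall`, `standard_met`, `error_codes`),
#'   `defects` (data.frame `id`/`kind`) and `seed`.
#' @export
generate_submission <- function(n, defects = defect_spec(),
                                rulesets = faang_rulesets(),
                                graph = build_fixture_ontology(),
                                seed = 1L, with_contributors = TRUE) {
  defects <- if (inherits(defects, "defect_spec")) defects
             else do.call(defect_spec, as.list(defects))
  if (sum(defects) > n) {
    stop("total defect count (", sum(defects), ") exceeds n (", n, ")",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  af <- rulesets$animal$full
  ef <- rulesets$experiment$full
  roots <- unique(unlist(lapply(c(ruleset_rules(af), ruleset_rules(ef)),
                                function(r) vapply(r$ontology_constraints,
                                                   `[[`, character(1),
                                                   "root"))))
  desc <- stats::setNames(lapply(roots, function(r) {
    d <- .descendants_of(graph, r)
    if (!length(d)) r else d
  }), roots)
  role_pool <- .descendants_of(graph, "EFO:0002012")
  breed_leaves <- setdiff(.descendants_of(graph, "LBO:0000000"),
                          c("LBO:0001036", "LBO:0001038"))

  # defect assignment: animal i gets kind_of[i] (or "none")
  kind_of <- rep("none", n)
  slots <- sample.int(n, sum(defects))
  kind_of[slots] <- rep(names(defects), times = defects)

  records <- list()
  expected <- list()
  defect_rows <- list()
  animal_ids <- character(0)

  for (i in seq_len(n)) {
    aid <- sprintf("ANIMAL%04d", i)
    sid <- sprintf("SPECIMEN%04d", i)
    xid <- sprintf("EXPT%04d", i)
    animal <- .gen_record(aid, "animal", af, graph, desc)
    animal <- .replace_attr(animal, "material",
                            record_attribute("material", "organism"))
    # a fifth of the animals are crossbred cattle or goats
    if (stats::runif(1) < 0.2) {
      species <- .pick(c("NCBITaxon:9913", "NCBITaxon:9925"))
      animal <- .replace_attr(animal, "organism",
                              record_attribute("organism",
                                               graph$terms[[species]]$label,
                                               term_id = species))
      pair <- sample(breed_leaves, 2L)
      cross_name <- paste0(graph$terms[[pair[1]]]$label, " sire × ",
                           graph$terms[[pair[2]]]$label, " dam")
      animal <- .replace_attr(animal, "breed",
                              record_attribute("breed", cross_name,
                                               term_id = crossbreed_terms()[[species]]))
    }
    if (length(animal_ids) && stats::runif(1) < 0.25) {
      animal$child_of <- .pick(animal_ids)
    }
    if (with_contributors) {
      animal$contributors <- data.frame(
        name = paste("Contributor", i),
        role = .pick(role_pool), stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < 0.1) {
      animal$attributes <- c(animal$attributes, list(
        record_attribute("barn temperature",
                         as.character(sample.int(30L, 1L)))))
    }
    specimen <- .gen_record(sid, "specimen", af, graph, desc)
    specimen <- .replace_attr(specimen, "material",
                              record_attribute("material",
                                               "specimen from organism"))
    specimen$derived_from <- aid
    expt <- .gen_record(xid, "experiment", ef, graph, desc)
    expt$derived_from <- sid

    exp_animal <- list(id = aid, overall = "pass", standard_met = "full",
                       error_codes = "")
    exp_specimen <- list(id = sid, overall = "pass", standard_met = "full",
                         error_codes = "")
    exp_expt <- list(id = xid, overall = "pass", standard_met = "full",
                     error_codes = "")

    kind <- kind_of[i]
    switch(kind,
      none = NULL,
      drop_mandatory = {
        animal <- .replace_attr(animal, "organism", NULL)
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "none", "mandatory_field_missing")
      },
      missing_term_on_mandatory = {
        animal <- .replace_attr(animal, "sex",
                                record_attribute("sex", "not provided"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "legacy", "missing_value_not_accepted")
      },
      missing_term_on_recommended = {
        animal <- .replace_attr(animal, "birth date",
                                record_attribute("birth date",
                                                 "not collected"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("pass_with_warnings", "full", "")
      },
      bad_ontology_term = {
        animal <- .replace_attr(animal, "health status",
                                record_attribute("health status", "Angus",
                                                 term_id = "LBO:9000001"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "none", "term_not_descendant")
      },
      bad_enum = {
        animal <- .replace_attr(animal, "material",
                                record_attribute("material",
                                                 "tissue sample"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "none", "value_not_permitted")
      },
      bad_units = {
        animal <- .replace_attr(animal, "animal age at collection",
                                record_attribute("animal age at collection",
                                                 "12",
                                                 units = "fortnights"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "none", "units_not_permitted")
      },
      malformed_crossbreed = {
        animal <- .replace_attr(animal, "breed",
                                record_attribute("breed",
                                                 "Angus sire x Hereford",
                                                 term_id = "LBO:0001036"))
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "none", "breed_name_unparseable")
      },
      dangling_link = {
        specimen$derived_from <- sprintf("MISSING%04d", i)
        exp_specimen[c("overall", "standard_met", "error_codes")] <-
          list("fail", "full", "dangling_reference")
      },
      legacy_only = {
        animal <- .replace_attr(animal, "developmental stage", NULL)
        exp_animal[c("overall", "standard_met", "error_codes")] <-
          list("fail", "legacy", "mandatory_field_missing")
      }
    )
    if (kind != "none") {
      target <- if (kind == "dangling_link") sid else aid
      defect_rows[[length(defect_rows) + 1L]] <-
        data.frame(id = target, kind = kind, stringsAsFactors = FALSE)
    }
    records <- c(records, list(animal, specimen, expt))
    expected <- c(expected, list(exp_animal, exp_specimen, exp_expt))
    animal_ids <- c(animal_ids, aid)
  }
  structure(
    list(records = records,
         expected = do.call(rbind, lapply(expected, as.data.frame,
                                          stringsAsFactors = FALSE)),
         defects = if (length(defect_rows)) do.call(rbind, defect_rows)
                   else data.frame(id = character(0), kind = character(0)),
         seed = seed),
    class = "labeled_submission"
  )
}

#' @export
print.labeled_submission <- function(x, ...) {
  cat("<labeled_submission> ", length(x$records), " records (seed ",
      x$seed, "), ", nrow(x$defects), " injected defects\n", sep = "")
  invisible(x)
}

#' Write a labelled submission to disk in the formats the readers consume
#'
#' Emits `animals_and_samples.tsv` (animal + specimen rows, animal
#' template), `experiments.tsv`, `records.json` and an
#' `expected_labels.json` sidecar recording the seed and per-record
#' expected outcomes.
#'
#' @param submission A `labeled_submission`.
#' @param dir Output directory (created if needed).
#' @param rulesets As [faang_rulesets()].
#' @return `dir`, invisibly.
#' @export
write_labeled_submission <- function(submission, dir,
                                     rulesets = faang_rulesets()) {
  stopifnot(inherits(submission, "labeled_submission"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  domains <- vapply(submission$records, `[[`, character(1), "record_domain")
  write_records_spreadsheet(submission$records[domains != "experiment"],
                            rulesets$animal$full,
                            file.path(dir, "animals_and_samples.tsv"))
  write_records_spreadsheet(submission$records[domains == "experiment"],
                            rulesets$experiment$full,
                            file.path(dir, "experiments.tsv"))
  write_records_json(submission$records, file.path(dir, "records.json"))
  sidecar <- list(seed = submission$seed,
                  expected = submission$expected,
                  defects = submission$defects)
  jsonlite::write_json(sidecar, file.path(dir, "expected_labels.json"),
                       auto_unbox = TRUE, dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
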