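g <- FIXTURE_GRAPH
animal_full <- FIXTURE_RULESETS$animal$full
animal_legacy <- FIXTURE_RULESETS$animal$legacy

test_that("exactly four controlled strings stand in for missing values", {
  recognised <- c("not applicable", "not collected", "not provided",
                  "restricted access")
  probes <- c(recognised, toupper(recognised),
              "  Restricted Access ", "not known", "n/a", "", "Texel",
              "none", "missing", "not  provided")
  hits <- classify_missing_value(probes)
  expect_setequal(unique(hits[!is.na(hits)]), recognised)
  expect_equal(classify_missing_value("  Restricted Access "),
               "restricted access")
  expect_true(is.na(classify_missing_value("Texel")))
  expect_true(is.na(classify_missing_value("not  provided")))  # exact strings only
  expect_equal(length(missing_value_terms()), 4L)
})

test_that("the tier x missing-value decision table is honoured", {
  rule_m <- field_rule("sex", "mandatory")
  rule_r <- field_rule("birth date", "recommended")
  rule_o <- field_rule("diet", "optional")
  status_of <- function(rule, value) {
    out <- validate_attribute(record_attribute(rule$name, value), rule, g)
    out$status[1]
  }
  # mandatory: only restricted access is tolerated, with a warning
  expect_equal(status_of(rule_m, "restricted access"), "warning")
  expect_equal(status_of(rule_m, "not provided"), "error")
  expect_equal(status_of(rule_m, "not collected"), "error")
  expect_equal(status_of(rule_m, "not applicable"), "error")
  # recommended: NA/RA pass, NC/NP warn
  expect_equal(status_of(rule_r, "not applicable"), "pass")
  expect_equal(status_of(rule_r, "restricted access"), "pass")
  expect_equal(status_of(rule_r, "not collected"), "warning")
  expect_equal(status_of(rule_r, "not provided"), "warning")
  # optional: everything is reported as info only
  for (term in missing_value_terms()) {
    expect_equal(status_of(rule_o, term), "info")
  }
})

test_that("value contracts produce the expected outcome codes", {
  health_rule <- ruleset_rules(animal_full)[[which(vapply(
    ruleset_rules(animal_full), `[[`, character(1), "name") ==
      "health status")]]
  codes_of <- function(attr, rule) {
    validate_attribute(attr, rule, g)$code
  }
  # descendant of PATO:0000461 passes
  expect_true("value_ok" %in% codes_of(
    record_attribute("health status", "healthy", term_id = "FXT:0000101"),
    health_rule))
  # constraint root itself passes but is flagged
  out <- validate_attribute(
    record_attribute("health status", "normal", term_id = "PATO:0000461"),
    health_rule, g)
  expect_true("ontology_root_term_used" %in% out$code)
  expect_false(any(out$status == "error"))
  # non-descendant and unknown terms error
  expect_true("term_not_descendant" %in% codes_of(
    record_attribute("health status", "Angus", term_id = "LBO:9000001"),
    health_rule))
  expect_true("term_unknown" %in% codes_of(
    record_attribute("health status", "x", term_id = "XX:999"),
    health_rule))

  enum_rule <- field_rule("material", "mandatory", "enum",
                          allowed_values = c("A", "B"))
  expect_true("value_not_permitted" %in% codes_of(
    record_attribute("material", "C"), enum_rule))

  num_rule <- field_rule("weight", "mandatory", "number",
                         valid_units = c("kilograms", "grams"))
  expect_true("units_not_permitted" %in% codes_of(
    record_attribute("weight", "5", units = "stone"), num_rule))
  expect_true("units_missing" %in% codes_of(
    record_attribute("weight", "5"), num_rule))
  expect_true("invalid_number" %in% codes_of(
    record_attribute("weight", "heavy", units = "grams"), num_rule))

  date_rule <- field_rule("birth date", "mandatory", "date",
                          valid_units = c("YYYY-MM-DD", "YYYY-MM", "YYYY"))
  expect_true("value_ok" %in% codes_of(
    record_attribute("birth date", "2015-03", units = "YYYY-MM"), date_rule))
  expect_true("invalid_date_format" %in% codes_of(
    record_attribute("birth date", "2015-03", units = "YYYY-MM-DD"),
    date_rule))
  expect_true("invalid_date_format" %in% codes_of(
    record_attribute("birth date", "2015-02-31", units = "YYYY-MM-DD"),
    date_rule))

  uri_rule <- field_rule("protocol", "mandatory", "uri")
  expect_true("invalid_uri" %in% codes_of(
    record_attribute("protocol", "see attachment"), uri_rule))
  doi_rule <- field_rule("publication", "recommended", "doi")
  expect_true("value_ok" %in% codes_of(
    record_attribute("publication", "10.1111/xyz.12736"), doi_rule))
})

test_that("an empty record fails every mandatory rule of the full standard", {
  rep <- validate_record(metadata_record("A0", "animal"), animal_full, g)
  expect_equal(sum(rep$outcomes$status == "error"), 27L)
  expect_equal(unique(rep$outcomes$code[rep$outcomes$status == "error"]),
               "mandatory_field_missing")
  expect_equal(rep$overall, "fail")
})

test_that("a record with valid mandatory fields and no recommended ones warns", {
  full <- valid_animal_record("A1")
  keep <- vapply(ruleset_rules(animal_full), function(r)
    r$requirement == "recommended", logical(1))
  rec_names <- tolower(vapply(ruleset_rules(animal_full)[keep], `[[`,
                              character(1), "name"))
  stripped <- full
  stripped$attributes <- Filter(function(a)
    !tolower(a$field_name) %in% rec_names, full$attributes)
  rep <- validate_record(stripped, animal_full, g)
  expect_equal(rep$overall, "pass_with_warnings")
  expect_equal(sum(rep$outcomes$code == "recommended_field_missing"), 7L)
  expect_equal(sum(rep$outcomes$status == "error"), 0L)
})

test_that("additional fields pass through as info without changing the verdict", {
  r <- valid_animal_record("A2")
  r$attributes <- c(r$attributes,
                    list(record_attribute("barn temperature", "21")))
  rep <- validate_record(r, animal_full, g)
  expect_equal(rep$overall, "pass")
  expect_true("additional_field" %in% rep$outcomes$code)
  # with an unknown ontology term the extra field draws a warning
  r$attributes <- c(r$attributes,
                    list(record_attribute("barn colour", "red",
                                          term_id = "XX:1")))
  rep <- validate_record(r, animal_full, g)
  expect_true("additional_field_term_unknown" %in% rep$outcomes$code)
})

test_that("section applicability conditions gate their rules", {
  rs <- ruleset("assay standard", "1.0", "full", "experiment", list(
    rule_section("core", list(
      field_rule("assay type", "mandatory", "enum",
                 allowed_values = c("RRBS", "WGS")))),
    rule_section("rrbs", list(
      field_rule("restriction enzyme", "mandatory")),
      condition = list(attribute = "assay type", value = "RRBS"))))
  rrbs <- metadata_record("E1", "experiment", list(
    record_attribute("assay type", "RRBS")))
  rep <- validate_record(rrbs, rs, g)
  expect_true("restriction enzyme" %in%
                rep$outcomes$field_name[rep$outcomes$status == "error"])
  wgs <- metadata_record("E2", "experiment", list(
    record_attribute("assay type", "WGS")))
  rep <- validate_record(wgs, rs, g)
  expect_false("restriction enzyme" %in% rep$outcomes$field_name)
  expect_equal(rep$overall, "pass")
})

test_that("contributor roles must descend from the organization-role term", {
  r <- valid_animal_record("A3")
  r$contributors <- data.frame(name = "Ann", role = "FXT:0000302",
                               stringsAsFactors = FALSE)
  expect_equal(validate_record(r, animal_full, g)$overall, "pass")
  r$contributors <- data.frame(name = "Bob", role = "PATO:0000461",
                               stringsAsFactors = FALSE)
  rep <- validate_record(r, animal_full, g)
  expect_true("contributor_role_invalid" %in% rep$outcomes$code)
})

test_that("records are classified full, legacy or none", {
  r <- valid_animal_record("A4")
  expect_equal(assign_standard(r, animal_full, animal_legacy, g), "full")
  # drop a field that only the full standard requires
  partial <- r
  partial$attributes <- Filter(function(a)
    tolower(a$field_name) != "developmental stage", r$attributes)
  expect_equal(assign_standard(partial, animal_full, animal_legacy, g),
               "legacy")
  expect_equal(assign_standard(metadata_record("A5", "animal"),
                               animal_full, animal_legacy, g), "none")
  expect_error(assign_standard(r, animal_full,
                               FIXTURE_RULESETS$experiment$legacy, g),
               "domain")
})

test_that("version labelling returns the newest release a record meets", {
  mk <- function(version, extra_mandatory = FALSE) {
    rules <- list(field_rule("sex", "mandatory"))
    if (extra_mandatory) {
      rules <- c(rules, list(field_rule("tattoo id", "mandatory")))
    }
    ruleset("standard", version, "full", "animal",
            list(rule_section("g", rules)))
  }
  rec <- metadata_record("A6", "animal",
                         list(record_attribute("sex", "male")))
  expect_equal(label_version(rec, list(mk("3.4"), mk("3.5")), g), "3.5")
  expect_equal(label_version(rec, list(mk("3.4"), mk("3.5", TRUE)), g),
               "3.4")
  expect_true(is.na(label_version(metadata_record("A7", "animal"),
                                  list(mk("3.4"), mk("3.5")), g)))
  expect_error(label_version(rec, list(), g), "empty")
  expect_error(label_version(rec, list(mk("3.5"), mk("3.4")), g),
               "ascending")
})

test_that("cross-reference checks find dangling links, cycles and bad domains", {
  a <- metadata_record("A", "animal")
  s <- metadata_record("S", "specimen", derived_from = "A")
  e <- metadata_record("E", "experiment", derived_from = "S")
  expect_equal(nrow(validate_links(list(a, s, e))), 0L)

  dangle <- metadata_record("E2", "experiment", derived_from = "GHOST")
  out <- validate_links(list(dangle))
  expect_equal(out$code, "dangling_reference")

  s1 <- metadata_record("S1", "specimen", derived_from = "S2")
  s2 <- metadata_record("S2", "specimen", derived_from = "S1")
  out <- validate_links(list(s1, s2))
  expect_true("derived_from_cycle" %in% out$code)

  wrong <- metadata_record("E3", "experiment", derived_from = "A")
  out <- validate_links(list(a, wrong))
  expect_true("derived_from_domain_invalid" %in% out$code)

  twin <- metadata_record("A", "animal")
  out <- validate_links(list(a, twin))
  expect_true("duplicate_record_id" %in% out$code)

  kid <- metadata_record("A2", "animal", child_of = c("A", "GHOST"))
  out <- validate_links(list(a, kid))
  expect_true("dangling_reference" %in% out$code)
})

test_that("validation is deterministic", {
  r <- valid_animal_record("A8")
  rep1 <- validate_record(r, animal_full, g)
  rep2 <- validate_record(r, animal_full, g)
  expect_identical(rep1, rep2)
  expect_identical(write_validation_report(
    validate_submission(list(r), FIXTURE_RULESETS, g)),
    write_validation_report(
      validate_submission(list(r), FIXTURE_RULESETS, g)))
})

test_that("error counts agree with a naive re-implementation of the rules", {
  sub <- generate_submission(
    40, defect_spec(drop_mandatory = 3, missing_term_on_mandatory = 3,
                    missing_term_on_recommended = 3, bad_ontology_term = 3,
                    bad_enum = 3, bad_units = 3, malformed_crossbreed = 3,
                    legacy_only = 3),
    rulesets = FIXTURE_RULESETS, graph = g, seed = 303)
  for (r in sub$records) {
    rs <- if (r$record_domain == "experiment")
      FIXTURE_RULESETS$experiment$full else animal_full
    rep <- validate_record(r, rs, g)
    expect_equal(sum(rep$outcomes$status == "error"),
                 naive_error_count(r, rs, g),
                 info = paste("record", r$id))
  }
})

test_that("meeting the full standard implies meeting legacy", {
  sub <- generate_submission(
    30, defect_spec(drop_mandatory = 2, bad_enum = 2, legacy_only = 2),
    rulesets = FIXTURE_RULESETS, graph = g, seed = 404)
  for (r in sub$records) {
    pair <- if (r$record_domain == "experiment")
      FIXTURE_RULESETS$experiment else FIXTURE_RULESETS$animal
    std <- assign_standard(r, pair$full, pair$legacy, g)
    if (std == "full") {
      legacy_rep <- validate_record(r, pair$legacy, g)
      expect_equal(sum(legacy_rep$outcomes$status == "error"), 0L)
    }
  }
})
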