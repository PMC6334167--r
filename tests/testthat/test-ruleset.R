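animal_full_path <- system.file("extdata", "faang_animal_full.ruleset.json",
                                package = "faangr")

test_that("the bundled full rulesets load with the published structure", {
  rs <- load_ruleset(animal_full_path)
  expect_s3_class(rs, "ruleset")
  expect_equal(rs$version, "3.5")
  expect_equal(rs$standard_tier, "full")
  expect_equal(rs$record_domain, "animal")
  nm <- vapply(ruleset_rules(rs), `[[`, character(1), "name")
  expect_true(all(c("sex", "organism", "breed", "developmental stage",
                    "birth date", "health status", "publication",
                    "birth location", "specimen volume") %in% nm))
})

test_that("a document with zero sections loads as an empty ruleset", {
  rs <- load_ruleset(
    '{"name": "empty", "version": "1.0", "standard_tier": "full",
      "record_domain": "animal", "rule_groups": []}')
  expect_equal(length(ruleset_rules(rs)), 0L)
  expect_equal(unname(count_fields_by_tier(rs)), c(0L, 0L, 0L))
})

test_that("schema violations are rejected naming the offending part", {
  dup <- '{"name": "x", "version": "1.0", "standard_tier": "full",
           "record_domain": "animal", "rule_groups": [
             {"name": "g", "rules": [
               {"name": "sex", "requirement": "mandatory"},
               {"name": "sex", "requirement": "optional"}]}]}'
  expect_error(load_ruleset(dup), "sex")
  expect_error(load_ruleset('{"name": "x", "version": "1.0"'), "malformed")
  bad_tier <- '{"name": "x", "version": "1.0", "standard_tier": "full",
                "record_domain": "animal", "rule_groups": [
                  {"name": "g", "rules": [
                    {"name": "sex", "requirement": "compulsory"}]}]}'
  expect_error(load_ruleset(bad_tier), "compulsory")
  expect_error(field_rule("choice", "mandatory", "enum"), "allowed value")
  expect_error(field_rule("term", "mandatory", "ontology_id"), "constraint")
  expect_error(ruleset("x", "1.0.0", "full", "animal"), "major.minor")
})

test_that("load -> serialize -> load is the identity", {
  for (f in c("faang_animal_full.ruleset.json",
              "faang_experiment_full.ruleset.json",
              "faang_animal_legacy.ruleset.json")) {
    rs <- load_ruleset(system.file("extdata", f, package = "faangr"))
    rs2 <- load_ruleset(write_ruleset(rs))
    expect_equal(rs2, rs)
  }
})

test_that("tier counts cover every rule exactly once", {
  counts <- count_fields_by_tier(load_ruleset(animal_full_path))
  expect_equal(sum(counts),
               length(ruleset_rules(load_ruleset(animal_full_path))))
  # property over synthetic rulesets
  set.seed(7)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    rules <- lapply(seq_len(n), function(j)
      field_rule(paste0("f", j), sample(c("mandatory", "recommended",
                                          "optional"), 1)))
    rs <- ruleset("syn", "1.0", "full", "animal",
                  list(rule_section("g", rules)))
    expect_equal(sum(count_fields_by_tier(rs)), n)
  }
})

test_that("diffing a ruleset against itself reports no changes", {
  rs <- load_ruleset(animal_full_path)
  d <- diff_rulesets(rs, rs)
  expect_equal(length(d$added), 0L)
  expect_equal(length(d$removed), 0L)
  expect_equal(nrow(d$tier_changed), 0L)
  expect_equal(length(d$constraint_changed), 0L)
})

test_that("diff captures tier demotions, additions and is antisymmetric", {
  mk <- function(rules) ruleset("v", "1.0", "full", "animal",
                                list(rule_section("g", rules)))
  old <- mk(list(field_rule("birth date", "mandatory", "date"),
                 field_rule("sex", "mandatory")))
  new <- mk(list(field_rule("birth date", "recommended", "date"),
                 field_rule("sex", "mandatory"),
                 field_rule("coat colour", "optional")))
  d <- diff_rulesets(old, new)
  expect_equal(d$added, "coat colour")
  expect_equal(length(d$removed), 0L)
  expect_equal(d$tier_changed,
               data.frame(name = "birth date", old = "mandatory",
                          new = "recommended", stringsAsFactors = FALSE))
  rev <- diff_rulesets(new, old)
  expect_setequal(rev$removed, d$added)
  expect_setequal(rev$added, d$removed)
  expect_error(diff_rulesets(old, FIXTURE_RULESETS$experiment$full),
               "domain")
})

test_that("constraint changes are reported separately from tier changes", {
  mk <- function(values) ruleset("v", "1.0", "full", "animal",
                                 list(rule_section("g", list(
                                   field_rule("material", "mandatory",
                                              "enum",
                                              allowed_values = values)))))
  d <- diff_rulesets(mk("organism"), mk(c("organism", "pool of specimens")))
  expect_equal(d$constraint_changed, "material")
  expect_equal(nrow(d$tier_changed), 0L)
})

test_that("legacy mandatory fields must be a subset of the full standard's", {
  legacy_path <- system.file("extdata", "faang_animal_legacy.ruleset.json",
                             package = "faangr")
  full <- load_ruleset(animal_full_path)
  expect_s3_class(load_ruleset(legacy_path, paired_full = full), "ruleset")
  rogue <- ruleset("rogue legacy", "3.5", "legacy", "animal",
                   list(rule_section("g", list(
                     field_rule("shoe size", "mandatory")))))
  expect_error(load_ruleset(write_ruleset(rogue), paired_full = full),
               "shoe size")
})

test_that("table renderings are deterministic and carry one row per rule", {
  rs <- load_ruleset(animal_full_path)
  tsv <- render_ruleset_table(rs, "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(length(lines) - 1L, 66L)  # 27 + 7 + 32 data rows
  expect_identical(render_ruleset_table(rs, "tsv"), tsv)
  md <- render_ruleset_table(rs, "markdown")
  md_rows <- strsplit(md, "\n")[[1]][-(1:2)]
  md_triples <- t(vapply(md_rows, function(r) {
    cells <- trimws(strsplit(sub("^\\| ", "", sub(" \\|$", "", r)),
                             " | ", fixed = TRUE)[[1]])
    cells[1:3]
  }, character(3)))
  tsv_triples <- t(vapply(lines[-1], function(r)
    strsplit(r, "\t", fixed = TRUE)[[1]][1:3], character(3)))
  expect_equal(unname(md_triples), unname(tsv_triples))
  html <- render_ruleset_table(rs, "html")
  expect_equal(length(gregexpr("<tr>", html, fixed = TRUE)[[1]]), 67L)
  expect_error(render_ruleset_table(rs, "pdf"))
  empty <- ruleset("e", "1.0", "full", "animal")
  expect_equal(length(strsplit(render_ruleset_table(empty, "tsv"),
                               "\n")[[1]]), 1L)
})

test_that("version components compare numerically, not lexically", {
  vs <- lapply(c("3.5", "3.10"), function(v)
    ruleset("r", v, "full", "animal",
            list(rule_section("g", list(field_rule("f", "optional"))))))
  rec <- metadata_record("A", "animal",
                         list(record_attribute("f", "x")))
  expect_equal(label_version(rec, vs, FIXTURE_GRAPH), "3.10")
})
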