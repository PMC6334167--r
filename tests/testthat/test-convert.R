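gen_valid <- function(n = 4, seed = 31) {
  generate_submission(n, defect_spec(), FIXTURE_RULESETS, FIXTURE_GRAPH,
                      seed = seed, with_contributors = FALSE)$records
}

field_value_multiset <- function(records) {
  sort(unlist(lapply(records, function(r)
    vapply(r$attributes, function(a)
      paste(a$field_name, a$value, sep = "\r"), character(1)))))
}

test_that("BioSamples documents carry characteristics, IRIs and relationships", {
  records <- gen_valid()
  non_expt <- Filter(function(r) r$record_domain != "experiment", records)
  doc <- convert_to_biosamples(non_expt)
  expect_equal(doc$archive_kind, "biosamples_json")
  parsed <- jsonlite::fromJSON(doc$payload, simplifyVector = FALSE)
  expect_equal(length(parsed), length(non_expt))
  animal <- parsed[[1]]
  expect_equal(animal$name, non_expt[[1]]$id)
  sex <- animal$characteristics[["sex"]][[1]]
  expect_true(grepl("^http://purl.obolibrary.org/obo/PATO_",
                    sex$ontologyTerms[[1]]))
  specimen <- parsed[[2]]
  rel <- specimen$relationships[[1]]
  expect_equal(rel$type, "derived from")
  expect_equal(rel$target, non_expt[[1]]$id)
})

test_that("conversion preserves the (field, value) multiset and invents nothing", {
  records <- Filter(function(r) r$record_domain != "experiment",
                    gen_valid(seed = 32))
  parsed <- jsonlite::fromJSON(convert_to_biosamples(records)$payload,
                               simplifyVector = FALSE)
  converted <- sort(unlist(lapply(parsed, function(s)
    unlist(lapply(names(s$characteristics), function(f)
      vapply(s$characteristics[[f]], function(e)
        paste(f, e$text, sep = "\r"), character(1)))))))
  expect_equal(converted, field_value_multiset(records))
})

test_that("records without attributes or relationships still convert", {
  doc <- convert_to_biosamples(list(metadata_record("LONER", "animal")))
  parsed <- jsonlite::fromJSON(doc$payload, simplifyVector = FALSE)
  expect_equal(parsed[[1]]$name, "LONER")
  expect_equal(length(parsed[[1]]$characteristics), 0L)
})

test_that("dangling relationship targets abort conversion", {
  s <- metadata_record("S1", "specimen", derived_from = "GHOST")
  expect_error(convert_to_biosamples(list(s)), "GHOST")
})

test_that("converters are deterministic", {
  records <- gen_valid(seed = 33)
  non_expt <- Filter(function(r) r$record_domain != "experiment", records)
  expect_identical(convert_to_biosamples(non_expt)$payload,
                   convert_to_biosamples(non_expt)$payload)
  expts <- Filter(function(r) r$record_domain == "experiment", records)
  expect_identical(convert_to_ena_xml(expts)$payload,
                   convert_to_ena_xml(expts)$payload)
})

test_that("ENA documents serialize attributes as TAG/VALUE(/UNITS) triples", {
  expt <- metadata_record("E1", "experiment", list(
    record_attribute("assay type", "RNA-seq"),
    record_attribute("read length", "150", units = "bases")),
    derived_from = "S1")
  doc <- convert_to_ena_xml(list(expt))
  expect_equal(doc$archive_kind, "ena_xml")
  x <- xml2::read_xml(doc$payload)
  blocks <- xml2::xml_find_all(x, "//EXPERIMENT_ATTRIBUTE")
  expect_equal(length(blocks), 2L)
  expect_equal(xml2::xml_text(xml2::xml_find_first(blocks[[1]], "TAG")),
               "assay type")
  # UNITS appears exactly when units are set
  expect_equal(length(xml2::xml_find_all(blocks[[1]], "UNITS")), 0L)
  expect_equal(xml2::xml_text(xml2::xml_find_first(blocks[[2]], "UNITS")),
               "bases")
  expect_equal(xml2::xml_attr(xml2::xml_find_first(x, "//EXPERIMENT"),
                              "alias"), "E1")
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(x, "//SAMPLE_DESCRIPTOR"), "refname"), "S1")
  expect_true(check_ena_xml(doc))
})

test_that("an empty experiment set is still schema-valid", {
  doc <- convert_to_ena_xml(list())
  expect_true(check_ena_xml(doc))
})

test_that("generated experiment submissions validate against the shipped schema", {
  expts <- Filter(function(r) r$record_domain == "experiment",
                  gen_valid(seed = 34))
  doc <- convert_to_ena_xml(expts)
  expect_true(check_ena_xml(doc))
  x <- xml2::read_xml(doc$payload)
  expect_equal(length(xml2::xml_find_all(x, "//EXPERIMENT")), length(expts))
  # attribute counts preserved
  for (i in seq_along(expts)) {
    node <- xml2::xml_find_all(x, "//EXPERIMENT")[[i]]
    expect_equal(length(xml2::xml_find_all(node, ".//EXPERIMENT_ATTRIBUTE")),
                 length(expts[[i]]$attributes))
  }
})

test_that("non-experiment records are refused by the ENA converter", {
  expect_error(convert_to_ena_xml(list(metadata_record("A1", "animal"))),
               "domain")
})
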