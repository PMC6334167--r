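test_that("the canonical two-breed cross parses and re-serializes identically", {
  d <- parse_crossbreed_name("Texel sire × Scottish Blackface dam")
  expect_equal(d$kind, "cross")
  expect_equal(d$sire$kind, "leaf")
  expect_equal(d$sire$name, "Texel")       # sire always listed first
  expect_equal(d$dam$name, "Scottish Blackface")
  expect_equal(format(d), "Texel sire × Scottish Blackface dam")
})

test_that("ASCII 'x' is accepted on input but serialized as the U+00D7 sign", {
  d <- parse_crossbreed_name("Angus sire x Hereford dam")
  expect_equal(format(d), "Angus sire × Hereford dam")
})

test_that("crossbred parents nest with parentheses and unknown parents parse", {
  d <- parse_crossbreed_name(
    "(Landrace sire × Duroc dam) sire × Large White dam")
  expect_equal(d$sire$kind, "cross")
  expect_equal(d$sire$sire$name, "Landrace")
  expect_equal(d$dam$name, "Large White")
  expect_equal(format(d),
               "(Landrace sire × Duroc dam) sire × Large White dam")
  u <- parse_crossbreed_name("unknown sire × Boer dam")
  expect_equal(u$sire$name, "unknown")
})

test_that("grammar violations are rejected with positions or reasons", {
  expect_error(parse_crossbreed_name("Texel × Duroc"), "sire")
  expect_error(parse_crossbreed_name("Texel sire × Duroc"), "dam")
  expect_error(parse_crossbreed_name("(Texel sire × Duroc dam sire × A dam"),
               "unbalanced")
  expect_error(parse_crossbreed_name("sire × Duroc dam"), "empty parent")
  expect_error(parse_crossbreed_name(""), "empty")
  expect_error(parse_crossbreed_name(
    "A sire × B dam sire × C dam"), "ambiguous")
})

test_that("parse after format is the identity on random trees up to depth 4", {
  set.seed(13)
  breeds <- c("Texel", "Scottish Blackface", "Angus", "Duroc",
              "Large White", "Boer", "unknown")
  random_tree <- function(depth) {
    if (depth == 0L || stats::runif(1) < 0.4) {
      return(list(kind = "leaf",
                  name = sample(breeds, 1), term_id = NA_character_))
    }
    list(kind = "cross", sire = random_tree(depth - 1L),
         dam = random_tree(depth - 1L))
  }
  for (i in 1:50) {
    tree <- list(kind = "cross", sire = random_tree(3L),
                 dam = random_tree(3L))
    class(tree) <- "breed_descriptor"
    fix_class <- function(x) {
      class(x) <- "breed_descriptor"
      if (x$kind == "cross") {
        x$sire <- fix_class(x$sire); x$dam <- fix_class(x$dam)
      }
      x
    }
    tree <- fix_class(tree)
    reparsed <- parse_crossbreed_name(format(tree))
    expect_equal(format(reparsed), format(tree))
    expect_equal(reparsed, tree, ignore_attr = FALSE)
  }
})

test_that("crossbred records must carry the species crossbreed term", {
  g <- FIXTURE_GRAPH
  cattle_cross <- metadata_record("C1", "animal", list(
    record_attribute("organism", "Bos taurus", term_id = "NCBITaxon:9913"),
    record_attribute("breed", "Angus sire × Hereford dam",
                     term_id = "LBO:0001036")))
  out <- validate_breed(cattle_cross, "NCBITaxon:9913", g)
  expect_true("crossbreed_ok" %in% out$code)
  expect_false(any(out$status == "error"))

  goat_wrong <- metadata_record("G1", "animal", list(
    record_attribute("breed", "Boer sire × Saanen dam",
                     term_id = "LBO:9000007")))
  out <- validate_breed(goat_wrong, "NCBITaxon:9925", g)
  expect_true("crossbreed_term_required" %in% out$code)
  expect_match(out$message[out$code == "crossbreed_term_required"],
               "LBO:0001038")
})

test_that("purebred records need a known LBO term; preferred labels are free", {
  g <- FIXTURE_GRAPH
  pure <- metadata_record("P1", "animal", list(
    record_attribute("breed", "Bhadawari", term_id = "LBO:9000015",
                     preferred_label = "Bhadawari buffalo")))
  out <- validate_breed(pure, "NCBITaxon:89462", g)
  expect_equal(report_error_codes(list(outcomes = out)), character(0))
  expect_true("purebred_ok" %in% out$code)

  bad <- metadata_record("P2", "animal", list(
    record_attribute("breed", "Mystery", term_id = "PATO:0000461")))
  out <- validate_breed(bad, NA, g)
  expect_true("breed_term_not_lbo" %in% out$code)

  no_term <- metadata_record("P3", "animal", list(
    record_attribute("breed", "Mystery")))
  out <- validate_breed(no_term, NA, g)
  expect_true("breed_term_missing" %in% out$code)
})

test_that("cross-format names for unmapped species warn instead of erroring", {
  sheep_cross <- metadata_record("S1", "animal", list(
    record_attribute("breed", "Texel sire × Suffolk dam",
                     term_id = "LBO:9000004")))
  out <- validate_breed(sheep_cross, "NCBITaxon:9940", FIXTURE_GRAPH)
  expect_true("crossbreed_term_unmapped_species" %in% out$code)
  expect_false(any(out$status == "error"))
})
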