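# Regenerates the bundled text fixtures under inst/extdata from the
# builders in R/fixtures.R.  Run from the package root:
#   Rscript data-raw/make_fixtures.R
pkgload::load_all(".", quiet = TRUE)

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rs <- build_replica_rulesets()
write_ruleset(rs$animal_full, file.path(out, "faang_animal_full.ruleset.json"))
write_ruleset(rs$animal_legacy, file.path(out, "faang_animal_legacy.ruleset.json"))
write_ruleset(rs$experiment_full, file.path(out, "faang_experiment_full.ruleset.json"))
write_ruleset(rs$experiment_legacy, file.path(out, "faang_experiment_legacy.ruleset.json"))

write_ontology(build_fixture_ontology(), file.path(out, "faang_ontology.graph.json"))

cat("fixture sizes (bytes):\n")
print(file.info(list.files(out, full.names = TRUE))["size"])
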