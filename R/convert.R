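#' Submission documents
#'
#' Validated records are converted into the document styles the EMBL-EBI
#' archives accept: BioSamples-style JSON for animals and specimens, and a
#' minimal ENA/SRA-style EXPERIMENT_SET XML for experiments.  Converters do
#' not re-validate; that is the caller's duty.
#'
#' @name submission-documents
NULL

.submission_document <- function(archive_kind, payload) {
  structure(list(archive_kind = archive_kind, payload = payload),
            class = "submission_document")
}

#' @export
print.submission_document <- function(x, ...) {
  cat("<submission_document> ", x$archive_kind, ", ",
      nchar(x$payload), " characters\n", sep = "")
  invisible(x)
}

#' Convert records to a BioSamples-style JSON document
#'
#' One sample object per record:
#' `{name, characteristics: {field: [{text, unit?, ontologyTerms?}]},
#'   relationships: [{type: "derived from" | "child of", target}]}`.
#' Ontology CURIEs are expanded to full IRIs.  Key ordering follows
#' attribute order, so output is deterministic.
#'
#' @param records List of validated [metadata_record()]s.
#' @return A `submission_document` with `archive_kind = "biosamples_json"`.
#' @export
convert_to_biosamples <- function(records) {
  ids <- vapply(records, `[[`, character(1), "id")
  samples <- lapply(records, function(r) {
    characteristics <- list()
    for (a in r$attributes) {
      entry <- list(text = a$value)
      if (!is.na(a$units)) entry$unit <- a$units
      if (!is.na(a$term_id)) entry$ontologyTerms <- list(curie_to_iri(a$term_id))
      characteristics[[a$field_name]] <-
        c(characteristics[[a$field_name]] %||% list(), list(entry))
    }
    relationships <- list()
    if (!is.na(r$derived_from)) {
      if (!r$derived_from %in% ids) {
        stop("record '", r$id, "': derived_from target '", r$derived_from,
             "' is not among the records being converted", call. = FALSE)
      }
      relationships[[length(relationships) + 1L]] <-
        list(type = "derived from", target = r$derived_from)
    }
    for (p in r$child_of) {
      if (!p %in% ids) {
        stop("record '", r$id, "': child_of target '", p,
             "' is not among the records being converted", call. = FALSE)
      }
      relationships[[length(relationships) + 1L]] <-
        list(type = "child of", target = p)
    }
    out <- list(name = r$id, characteristics = characteristics)
    if (length(relationships)) out$relationships <- relationships
    out
  })
  .submission_document(
    "biosamples_json",
    as.character(jsonlite::toJSON(samples, auto_unbox = TRUE, pretty = TRUE)))
}

#' Convert experiment records to an ENA-style EXPERIMENT_SET XML document
#'
#' A minimal SRA-style dialect: one `EXPERIMENT` element (with an `alias`)
#' per record, a `SAMPLE_DESCRIPTOR` naming the source specimen, and one
#' `EXPERIMENT_ATTRIBUTE` `TAG`/`VALUE`(/`UNITS`) triple per attribute, in
#' attribute order.  The output validates against the schema shipped at
#' `system.file("extdata", "ena_experiment_set.xsd", package = "faangr")`.
#'
#' @param records List of [metadata_record()]s, all with domain
#'   `"experiment"`.
#' @return A `submission_document` with `archive_kind = "ena_xml"`.
#' @export
convert_to_ena_xml <- function(records) {
  for (r in records) {
    if (!identical(r$record_domain, "experiment")) {
      stop("record '", r$id, "' has domain '", r$record_domain,
           "'; only experiment records convert to ENA XML", call. = FALSE)
    }
  }
  doc <- xml2::xml_new_root("EXPERIMENT_SET")
  for (r in records) {
    exp <- xml2::xml_add_child(doc, "EXPERIMENT", alias = r$id)
    if (!is.na(r$derived_from)) {
      xml2::xml_add_child(exp, "SAMPLE_DESCRIPTOR", refname = r$derived_from)
    }
    if (length(r$attributes)) {
      attrs <- xml2::xml_add_child(exp, "EXPERIMENT_ATTRIBUTES")
      for (a in r$attributes) {
        ea <- xml2::xml_add_child(attrs, "EXPERIMENT_ATTRIBUTE")
        xml2::xml_add_child(ea, "TAG", a$field_name)
        xml2::xml_add_child(ea, "VALUE", a$value)
        if (!is.na(a$units)) xml2::xml_add_child(ea, "UNITS", a$units)
      }
    }
  }
  .submission_document("ena_xml", as.character(doc))
}

#' Validate an ENA-style document against the shipped minimal schema
#'
#' @param document A `submission_document` with `archive_kind = "ena_xml"`,
#'   or XML text.
#' @return `TRUE` invisibly; schema violations raise an error.
#' @export
check_ena_xml <- function(document) {
  txt <- if (inherits(document, "submission_document")) document$payload
         else document
  schema <- xml2::read_xml(system.file("extdata", "ena_experiment_set.xsd",
                                       package = "faangr", mustWork = TRUE))
  ok <- xml2::xml_validate(xml2::read_xml(txt), schema)
  if (!ok) {
    stop("ENA XML does not validate: ",
         paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a submission document to disk
#'
#' @param document A `submission_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submission_document <- function(document, path) {
  stopifnot(inherits(document, "submission_document"))
  writeLines(document$payload, path, useBytes = TRUE)
  invisible(path)
}
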