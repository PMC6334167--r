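#' @title Validation outcomes
#' @description Every check emits explicit outcomes — `pass`, `warning`,
#'   `error` or `info` — with stable snake_case codes so reports are machine
#'   diffable.  Validation never throws on bad metadata; problems are data.
#' @name outcomes
NULL

# outcomes are accumulated as character(5) rows and assembled into a
# data.frame once per record; rbind-per-outcome is far too slow at scale
.row <- function(field_name, status, code, message, rule_ref = "") {
  c(field_name, status, code, message, rule_ref)
}

.rows_to_df <- function(rows) {
  if (!length(rows)) {
    return(data.frame(field_name = character(0), status = character(0),
                      code = character(0), message = character(0),
                      rule_ref = character(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  data.frame(field_name = m[, 1], status = m[, 2], code = m[, 3],
             message = m[, 4], rule_ref = m[, 5], stringsAsFactors = FALSE)
}

.rule_ref <- function(ruleset) paste0(ruleset$name, " v", ruleset$version)

.DATE_PATTERNS <- c(
  "YYYY-MM-DD" = "^[0-9]{4}-[0-9]{2}-[0-9]{2}$",
  "YYYY-MM"    = "^[0-9]{4}-[0-9]{2}$",
  "YYYY"       = "^[0-9]{4}$"
)

.is_number_text <- function(v) {
  grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", v)
}

.attr_rows <- function(attr, rule, graph, rule_ref) {
  rows <- list()
  emit <- function(status, code, message) {
    rows[[length(rows) + 1L]] <<- .row(rule$name, status, code, message,
                                       rule_ref)
  }
  mv <- classify_missing_value(attr$value)

  if (!is.na(mv)) {
    switch(rule$requirement,
      mandatory = if (mv == "restricted access") {
        emit("warning", "restricted_access_on_mandatory",
             "mandatory value withheld as 'restricted access'")
      } else {
        emit("error", "missing_value_not_accepted",
             paste0("mandatory field supplied as '", mv, "'"))
      },
      recommended = if (mv %in% c("not collected", "not provided")) {
        emit("warning", "missing_value_warning",
             paste0("recommended field supplied as '", mv,
                    "'; please provide if available"))
      } else {
        emit("pass", "missing_value_accepted",
             paste0("'", mv, "' accepted on recommended field"))
      },
      optional = emit("info", "missing_value_info",
                      paste0("optional field supplied as '", mv, "'"))
    )
    return(rows)
  }

  ok <- TRUE
  flag <- function(code, message) { ok <<- FALSE; emit("error", code, message) }

  # units contract applies to any rule that lists valid units
  if (length(rule$valid_units)) {
    if (is.na(attr$units)) {
      flag("units_missing", paste0("units required (one of: ",
                                   paste(rule$valid_units, collapse = ", "),
                                   ")"))
    } else if (!attr$units %in% rule$valid_units) {
      flag("units_not_permitted",
           paste0("units '", attr$units, "' not permitted (expected one of: ",
                  paste(rule$valid_units, collapse = ", "), ")"))
    }
  } else if (!is.na(attr$units) && rule$value_type != "date") {
    emit("info", "units_ignored",
         paste0("units '", attr$units, "' supplied for a unitless field"))
  }

  switch(rule$value_type,
    text = NULL,
    number = if (!.is_number_text(attr$value)) {
      flag("invalid_number", paste0("'", attr$value, "' is not a number"))
    },
    date = {
      fmt <- if (!is.na(attr$units) && attr$units %in% names(.DATE_PATTERNS))
        attr$units else "YYYY-MM-DD"
      if (!grepl(.DATE_PATTERNS[[fmt]], attr$value)) {
        flag("invalid_date_format",
             paste0("'", attr$value, "' does not match ", fmt))
      } else if (fmt == "YYYY-MM-DD" &&
                 is.na(as.Date(attr$value, format = "%Y-%m-%d"))) {
        flag("invalid_date_format",
             paste0("'", attr$value, "' is not a real calendar date"))
      }
    },
    enum = if (!attr$value %in% rule$allowed_values) {
      flag("value_not_permitted",
           paste0("'", attr$value, "' is not one of: ",
                  paste(rule$allowed_values, collapse = ", ")))
    },
    uri = if (!grepl("^(https?|ftp)://[^[:space:]]+$", attr$value)) {
      flag("invalid_uri", paste0("'", attr$value, "' is not a URI"))
    },
    doi = if (!grepl("^(doi:|https?://(dx\\.)?doi\\.org/)?10\\.[0-9]{4,}/",
                     attr$value)) {
      flag("invalid_doi", paste0("'", attr$value, "' is not a DOI"))
    },
    ontology_id = {
      if (is.na(attr$term_id)) {
        flag("ontology_term_missing",
             "an ontology term id is required for this field")
      } else if (!attr$term_id %in% names(graph$terms)) {
        flag("term_unknown",
             paste0("term '", attr$term_id, "' not found in the ontology"))
      } else {
        sat <- FALSE; at_root <- FALSE
        for (con in rule$ontology_constraints) {
          if (identical(attr$term_id, con$root)) {
            if (con$include_root) { sat <- TRUE; at_root <- TRUE }
          } else if (con$root %in% names(graph$terms) &&
                     is_descendant(graph, attr$term_id, con$root)) {
            sat <- TRUE
          }
        }
        if (!sat) {
          roots <- vapply(rule$ontology_constraints, `[[`, character(1),
                          "root")
          flag("term_not_descendant",
               paste0("term '", attr$term_id, "' is not a descendant of ",
                      paste(roots, collapse = " or ")))
        } else if (at_root) {
          emit("info", "ontology_root_term_used",
               paste0("constraint root '", attr$term_id,
                      "' used directly; a more specific descendant is ",
                      "preferred"))
        }
      }
    }
  )

  if (ok) emit("pass", "value_ok", paste0("'", attr$value, "' accepted"))
  rows
}

#' Validate one attribute against one field rule
#'
#' Applies the requirement-tier x missing-value decision table, then the
#' value contract.  The decision table: a mandatory field passes with a
#' concrete valid value, warns on `"restricted access"` (the value exists
#' but is withheld) and errors on the other three terms; a recommended field
#' passes on a concrete value, `"not applicable"` or `"restricted access"`
#' and warns on `"not collected"` / `"not provided"`; an optional field
#' accepts anything (missing-value terms are reported as `info`).
#' Constraint checks (enum membership, units, date format, ontology
#' descendant) run only on concrete values.
#'
#' @param attr A [record_attribute()]; its field name must match the rule.
#' @param rule A [field_rule()].
#' @param graph An [ontology_graph()] (used for `ontology_id` rules).
#' @param rule_ref Text naming the ruleset and version, echoed in outcomes.
#' @return A data.frame of outcomes (columns `field_name`, `status`, `code`,
#'   `message`, `rule_ref`).
#' @export
validate_attribute <- function(attr, rule, graph, rule_ref = "") {
  stopifnot(inherits(attr, "record_attribute"), inherits(rule, "field_rule"))
  if (!identical(.field_key(attr$field_name), .field_key(rule$name))) {
    stop("attribute '", attr$field_name, "' does not match rule '",
         rule$name, "'", call. = FALSE)
  }
  .rows_to_df(.attr_rows(attr, rule, graph, rule_ref))
}

#' Species -> crossbreed ontology term map
#'
#' Crossbred animals must carry the crossbreed term specific to their
#' species: LBO:0001036 for cattle and LBO:0001038 for goat.
#'
#' @return Named character vector mapping species CURIEs to LBO CURIEs.
#' @export
crossbreed_terms <- function() {
  c("NCBITaxon:9913" = "LBO:0001036",   # cattle
    "NCBITaxon:9925" = "LBO:0001038")   # goat
}

.breed_rows <- function(record, species_term, graph, cross_terms, rule_ref) {
  attrs <- .record_attrs(record, "breed")
  if (!length(attrs)) {
    return(list(.row("breed", "error", "breed_attribute_missing",
                     "record has no breed attribute", rule_ref)))
  }
  rows <- list()
  species_term <- if (is.null(species_term) || is.na(species_term))
    NA_character_ else normalize_curie(species_term)
  for (attr in attrs) {
    emit <- function(status, code, message) {
      rows[[length(rows) + 1L]] <<- .row("breed", status, code, message,
                                         rule_ref)
    }
    if (!is.na(classify_missing_value(attr$value))) next
    if (is_crossbreed_name(attr$value)) {
      parsed <- tryCatch(parse_crossbreed_name(attr$value),
                         error = function(e) e)
      if (inherits(parsed, "error")) {
        emit("error", "breed_name_unparseable",
             paste0("crossbreed name does not parse: ",
                    conditionMessage(parsed)))
        next
      }
      expected <- if (!is.na(species_term) &&
                      species_term %in% names(cross_terms))
        cross_terms[[species_term]]
      if (is.null(expected)) {
        emit("warning", "crossbreed_term_unmapped_species",
             "no crossbreed term registered for this species; cannot check")
      } else if (is.na(attr$term_id) ||
                 !identical(attr$term_id, unname(expected))) {
        emit("error", "crossbreed_term_required",
             paste0("crossbred animal must use the species crossbreed term ",
                    expected, ", got '",
                    if (is.na(attr$term_id)) "none" else attr$term_id, "'"))
      } else {
        emit("pass", "crossbreed_ok",
             paste0("crossbreed '", format(parsed), "' with term ",
                    expected))
      }
    } else {
      if (is.na(attr$term_id)) {
        emit("error", "breed_term_missing",
             "purebred breed requires an LBO ontology term id")
      } else if (!grepl("^LBO:", attr$term_id) ||
                 !attr$term_id %in% names(graph$terms)) {
        emit("error", "breed_term_not_lbo",
             paste0("'", attr$term_id,
                    "' is not a known Livestock Breed Ontology term"))
      } else {
        emit("pass", "purebred_ok",
             paste0("purebred '", attr$value, "' with term ", attr$term_id))
      }
    }
  }
  rows
}

#' Validate a record's breed nomenclature
#'
#' If the breed name uses the crossbreed grammar it must parse (see
#' [parse_crossbreed_name()]) and the attribute's ontology term must be the
#' species-specific crossbreed term.  A purebred name must carry an LBO term
#' present in the ontology graph.  The submitter's preferred label is always
#' allowed alongside the term id.
#'
#' @param record A [metadata_record()] with a breed attribute.
#' @param species_term Species CURIE (e.g. `NCBITaxon:9913`); `NA` skips the
#'   species-specific crossbreed-term check.
#' @param graph An [ontology_graph()].
#' @param cross_terms Species-to-crossbreed-term map; see
#'   [crossbreed_terms()].
#' @param rule_ref Text naming the ruleset and version.
#' @return A data.frame of outcomes.
#' @export
validate_breed <- function(record, species_term, graph,
                           cross_terms = crossbreed_terms(),
                           rule_ref = "") {
  .rows_to_df(.breed_rows(record, species_term, graph, cross_terms,
                          rule_ref))
}

# ruleset domain "animal" is the combined animals-and-samples standard
.domain_compatible <- function(record_domain, ruleset_domain) {
  if (ruleset_domain == "animal") record_domain %in% c("animal", "specimen")
  else identical(record_domain, ruleset_domain)
}

.section_applies <- function(section, record) {
  if (is.null(section$condition)) return(TRUE)
  attrs <- .record_attrs(record, section$condition$attribute)
  any(vapply(attrs, function(a)
    identical(trimws(a$value), section$condition$value), logical(1)))
}

.record_rows <- function(record, ruleset, graph, cross_terms) {
  ref <- .rule_ref(ruleset)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  attr_keys <- vapply(record$attributes, function(a)
    .field_key(a$field_name), character(1))
  matched_keys <- character(0)
  all_rule_keys <- character(0)
  for (section in ruleset$sections) {
    applies <- .section_applies(section, record)
    for (rule in section$rules) {
      key <- .field_key(rule$name)
      all_rule_keys <- c(all_rule_keys, key)
      if (!applies) next
      idx <- which(attr_keys == key)
      if (!length(idx)) {
        if (rule$requirement == "mandatory") {
          add(.row(rule$name, "error", "mandatory_field_missing",
                   "mandatory field not supplied", ref))
        } else if (rule$requirement == "recommended") {
          add(.row(rule$name, "warning", "recommended_field_missing",
                   "recommended field not supplied", ref))
        }
        next
      }
      matched_keys <- c(matched_keys, key)
      if (length(idx) > 1L && !rule$allow_multiple) {
        add(.row(rule$name, "error", "multiple_values_not_allowed",
                 paste0(length(idx), " values supplied for a ",
                        "single-valued field"), ref))
      }
      for (attr in record$attributes[idx]) {
        for (r in .attr_rows(attr, rule, graph, ref)) add(r)
      }
      if (key == "breed" && !is.null(cross_terms)) {
        org <- .record_attrs(record, "organism")
        species <- if (length(org)) org[[1]]$term_id else NA_character_
        for (r in .breed_rows(record, species, graph, cross_terms, ref)) {
          add(r)
        }
      }
    }
  }
  # attributes not covered by the standard pass through as additional fields
  for (i in seq_along(record$attributes)) {
    if (attr_keys[i] %in% matched_keys || attr_keys[i] %in% all_rule_keys) {
      next
    }
    attr <- record$attributes[[i]]
    add(.row(attr$field_name, "info", "additional_field",
             "field not covered by the standard; passed through", ref))
    if (!is.na(attr$term_id) && !attr$term_id %in% names(graph$terms)) {
      add(.row(attr$field_name, "warning", "additional_field_term_unknown",
               paste0("term '", attr$term_id,
                      "' not found in the ontology"), ref))
    }
  }
  # contributor roles are EFO organizational-role descendants
  if (!is.null(record$contributors) && nrow(record$contributors)) {
    for (i in seq_len(nrow(record$contributors))) {
      role <- record$contributors$role[i]
      bad <- is.na(role) || !role %in% names(graph$terms) ||
        !is_descendant(graph, role, "EFO:0002012")
      if (bad) {
        add(.row("contributors", "error", "contributor_role_invalid",
                 paste0("role '", role, "' for contributor '",
                        record$contributors$name[i],
                        "' is not a descendant of EFO:0002012"), ref))
      }
    }
  }
  rows
}

#' Validate a record against a ruleset
#'
#' Evaluates every applicable rule (section conditions are checked against
#' the record first): mandatory rules with no matching attribute are errors,
#' recommended ones warnings, optional ones silent; supplied attributes go
#' through [validate_attribute()]; attributes matching no rule are reported
#' as `additional_field` info (and their ontology terms are checked against
#' the graph when supplied); contributor roles must be descendants of
#' EFO:0002012; a breed rule additionally triggers crossbreed nomenclature
#' checks using the record's organism term.
#'
#' @param record A [metadata_record()].
#' @param ruleset A [ruleset()] whose domain is compatible with the record.
#' @param graph An [ontology_graph()].
#' @param cross_terms Species-to-crossbreed-term map used for breed checks;
#'   `NULL` disables them.
#' @return An object of class `record_report`: list with `id`, `outcomes`
#'   (data.frame), `overall` (`pass`, `pass_with_warnings`, `fail`),
#'   `standard_met` and `version_label` (filled by [assign_standard()] /
#'   [label_version()] when used through [validate_submission()]).
#' @export
validate_record <- function(record, ruleset, graph,
                            cross_terms = crossbreed_terms()) {
  stopifnot(inherits(record, "metadata_record"), inherits(ruleset, "ruleset"))
  if (!.domain_compatible(record$record_domain, ruleset$record_domain)) {
    stop("record '", record$id, "' (", record$record_domain,
         ") cannot be validated against a ", ruleset$record_domain,
         " ruleset", call. = FALSE)
  }
  out <- .rows_to_df(.record_rows(record, ruleset, graph, cross_terms))
  structure(
    list(id = record$id, outcomes = out, overall = .overall(out),
         standard_met = NA_character_, version_label = NA_character_),
    class = "record_report"
  )
}

.overall <- function(outcomes) {
  if (any(outcomes$status == "error")) "fail"
  else if (any(outcomes$status == "warning")) "pass_with_warnings"
  else "pass"
}

#' @export
print.record_report <- function(x, ...) {
  cat("<record_report> ", x$id, ": ", x$overall,
      if (!is.na(x$standard_met)) paste0(", standard: ", x$standard_met),
      " (", sum(x$outcomes$status == "error"), " errors, ",
      sum(x$outcomes$status == "warning"), " warnings)\n", sep = "")
  invisible(x)
}

# number of error outcomes without building a data.frame
.error_count <- function(record, ruleset, graph, cross_terms) {
  rows <- .record_rows(record, ruleset, graph, cross_terms)
  sum(vapply(rows, `[[`, character(1), 2L) == "error")
}

#' Classify a record against the full and legacy standards
#'
#' A record meets the `full` standard when it validates with zero errors
#' under the full ruleset; failing that, it meets `legacy` when it has zero
#' errors under the paired legacy ruleset (a minimal set of required fields
#' with the remainder optional); otherwise `none`.  Because the legacy
#' mandatory fields are a subset of the full ones, full implies legacy.
#'
#' @param record A [metadata_record()].
#' @param full,legacy Paired [ruleset()]s sharing a record domain.
#' @param graph An [ontology_graph()].
#' @param cross_terms See [validate_record()].
#' @return `"full"`, `"legacy"` or `"none"`.
#' @export
assign_standard <- function(record, full, legacy, graph,
                            cross_terms = crossbreed_terms()) {
  if (!identical(full$record_domain, legacy$record_domain)) {
    stop("full and legacy rulesets must share a record domain", call. = FALSE)
  }
  if (.error_count(record, full, graph, cross_terms) == 0L) return("full")
  if (.error_count(record, legacy, graph, cross_terms) == 0L) return("legacy")
  "none"
}

#' Label the last standard version a record meets
#'
#' Records archived under an older release may stop meeting an updated
#' standard; they are then labelled with the last version they did meet so
#' consumers can judge data quality.
#'
#' @param record A [metadata_record()].
#' @param versions List of [ruleset()]s sorted ascending by version, same
#'   record domain.
#' @param graph An [ontology_graph()].
#' @param cross_terms See [validate_record()].
#' @return The highest passing version string, or `NA` if none pass.
#' @export
label_version <- function(record, versions, graph,
                          cross_terms = crossbreed_terms()) {
  if (!length(versions)) stop("empty version list", call. = FALSE)
  vs <- vapply(versions, `[[`, character(1), "version")
  ord <- order(vapply(vs, function(v) .parse_version(v)[1] * 1000L +
                        .parse_version(v)[2], integer(1)))
  if (!identical(ord, seq_along(vs))) {
    stop("version list must be sorted ascending", call. = FALSE)
  }
  best <- NA_character_
  for (rs in versions) {
    if (.error_count(record, rs, graph, cross_terms) == 0L) {
      best <- rs$version
    }
  }
  best
}

#' Validate the cross-references of a submission
#'
#' Checks record interlinking: `derived_from` and `child_of` targets must
#' exist in the submission, derivation must be acyclic, and domains must
#' chain correctly (experiment from specimen; specimen from animal or
#' specimen; animals do not derive).  Duplicate record ids are reported.
#'
#' @param records List of [metadata_record()]s.
#' @return A data.frame of outcomes with an extra `record_id` column.
#' @export
validate_links <- function(records) {
  rows <- list()
  emit <- function(id, field, status, code, message) {
    rows[[length(rows) + 1L]] <<- c(id, .row(field, status, code, message,
                                             "links"))
  }
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    emit(d, "id", "error", "duplicate_record_id",
         paste0("record id '", d, "' appears more than once"))
  }
  domains <- stats::setNames(vapply(records, `[[`, character(1),
                                    "record_domain"), ids)
  parent <- stats::setNames(vapply(records, `[[`, character(1),
                                   "derived_from"), ids)
  for (r in records) {
    if (!is.na(r$derived_from)) {
      if (!r$derived_from %in% ids) {
        emit(r$id, "derived_from", "error", "dangling_reference",
             paste0("derived_from target '", r$derived_from,
                    "' is not in the submission"))
      } else if (r$record_domain == "animal") {
        emit(r$id, "derived_from", "error", "derived_from_domain_invalid",
             "animal records do not derive from other records")
      } else {
        src <- domains[[r$derived_from]]
        ok <- switch(r$record_domain,
                     experiment = src == "specimen",
                     specimen = src %in% c("animal", "specimen"))
        if (!ok) {
          emit(r$id, "derived_from", "error", "derived_from_domain_invalid",
               paste0(r$record_domain, " cannot derive from ", src))
        }
      }
    }
    for (p in r$child_of) {
      if (!p %in% ids) {
        emit(r$id, "child_of", "error", "dangling_reference",
             paste0("child_of target '", p, "' is not in the submission"))
      } else if (domains[[p]] != "animal" || r$record_domain != "animal") {
        emit(r$id, "child_of", "error", "derived_from_domain_invalid",
             "child_of links connect animals to animals")
      }
    }
  }
  # derived_from cycles
  for (start in ids) {
    seen <- start
    cur <- start
    repeat {
      nxt <- parent[[cur]]
      if (is.null(nxt) || is.na(nxt) || !nxt %in% ids) break
      if (nxt == start) {
        emit(start, "derived_from", "error", "derived_from_cycle",
             paste0("derivation cycle: ",
                    paste(c(seen, start), collapse = " -> ")))
        break
      }
      if (nxt %in% seen) break
      seen <- c(seen, nxt)
      cur <- nxt
    }
  }
  out <- .rows_to_df(lapply(rows, function(r) r[-1]))
  out$record_id <- vapply(rows, `[[`, character(1), 1L) %||%
    character(0)
  if (!length(rows)) out$record_id <- character(0)
  out[, c("record_id", "field_name", "status", "code", "message",
          "rule_ref")]
}

#' Validate a mixed-domain submission end to end
#'
#' Runs [validate_record()] on every record with the ruleset pair matching
#' its domain, merges [validate_links()] outcomes into the per-record
#' reports, classifies each record against the full and legacy standards
#' and labels the version met.
#'
#' @param records List of [metadata_record()]s.
#' @param rulesets Named list: `rulesets$animal$full`,
#'   `rulesets$animal$legacy`, `rulesets$experiment$full`,
#'   `rulesets$experiment$legacy` (pairs may be omitted for absent domains).
#' @param graph An [ontology_graph()].
#' @param cross_terms See [validate_record()].
#' @return An object of class `submission_report`: list with `reports` (one
#'   `record_report` per record) and `summary` (counts of pass /
#'   pass_with_warnings / fail).
#' @export
validate_submission <- function(records, rulesets, graph,
                                cross_terms = crossbreed_terms()) {
  link_out <- validate_links(records)
  reports <- lapply(records, function(r) {
    pair_key <- if (r$record_domain == "experiment") "experiment" else "animal"
    pair <- rulesets[[pair_key]]
    if (is.null(pair) || is.null(pair$full)) {
      stop("no ruleset pair supplied for domain '", pair_key, "'",
           call. = FALSE)
    }
    rep <- validate_record(r, pair$full, graph, cross_terms)
    full_errors <- sum(rep$outcomes$status == "error")
    mine <- link_out[link_out$record_id == r$id,
                     setdiff(names(link_out), "record_id"), drop = FALSE]
    rep$outcomes <- rbind(rep$outcomes, mine)
    rep$overall <- .overall(rep$outcomes)
    rep$standard_met <- if (full_errors == 0L) {
      "full"
    } else if (!is.null(pair$legacy) &&
               .error_count(r, pair$legacy, graph, cross_terms) == 0L) {
      "legacy"
    } else {
      "none"
    }
    rep$version_label <- if (rep$standard_met == "none") NA_character_
                         else pair$full$version
    rep
  })
  overall <- vapply(reports, `[[`, character(1), "overall")
  structure(
    list(reports = reports,
         summary = c(pass = sum(overall == "pass"),
                     pass_with_warnings = sum(overall == "pass_with_warnings"),
                     fail = sum(overall == "fail"))),
    class = "submission_report"
  )
}

#' @export
print.submission_report <- function(x, ...) {
  cat("<submission_report> ", length(x$reports), " records: ",
      x$summary[["pass"]], " pass, ",
      x$summary[["pass_with_warnings"]], " pass with warnings, ",
      x$summary[["fail"]], " fail\n", sep = "")
  invisible(x)
}

#' Serialize a submission report to JSON
#'
#' @param report A `submission_report` from [validate_submission()].
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_validation_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "submission_report"))
  doc <- list(
    records = lapply(report$reports, function(r) list(
      id = r$id, overall = r$overall,
      standard_met = if (is.na(r$standard_met)) NULL else r$standard_met,
      version_label = if (is.na(r$version_label)) "none" else r$version_label,
      outcomes = lapply(seq_len(nrow(r$outcomes)), function(i)
        as.list(r$outcomes[i, ])))),
    summary = as.list(report$summary)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
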