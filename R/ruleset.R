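REQUIREMENT_TIERS <- c("mandatory", "recommended", "optional")
VALUE_TYPES <- c("text", "number", "date", "enum", "ontology_id", "uri", "doi")
RECORD_DOMAINS <- c("animal", "specimen", "experiment")

#' Construct a single field rule
#'
#' A field rule is one row of the metadata checklist: a named field with a
#' requirement tier and a value contract.  Tiers are `mandatory` (must be
#' supplied), `recommended` (warn when absent) and `optional`.
#'
#' @param name Field name (non-empty; unique within a ruleset).
#' @param requirement One of `mandatory`, `recommended`, `optional`.
#' @param value_type One of `text`, `number`, `date`, `enum`, `ontology_id`,
#'   `uri`, `doi`.
#' @param description Free-text description.
#' @param allowed_values For `enum` rules: permitted values (>= 1 required).
#' @param valid_units Permitted unit strings (empty = unitless field).
#' @param ontology_constraints For `ontology_id` rules: list of
#'   `list(root = <CURIE>, include_root = <flag>)` entries (>= 1 required).
#'   A supplied term must be a descendant of at least one root.
#' @param allow_multiple May the field be supplied more than once?
#' @return An object of class `field_rule`.
#' @export
field_rule <- function(name, requirement, value_type = "text",
                       description = "", allowed_values = character(0),
                       valid_units = character(0),
                       ontology_constraints = list(),
                       allow_multiple = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("field rule name must be a non-empty string", call. = FALSE)
  }
  if (!requirement %in% REQUIREMENT_TIERS) {
    stop("field '", name, "': unknown requirement tier '", requirement, "'",
         call. = FALSE)
  }
  if (!value_type %in% VALUE_TYPES) {
    stop("field '", name, "': unknown value type '", value_type, "'",
         call. = FALSE)
  }
  if (identical(value_type, "enum") && length(allowed_values) == 0L) {
    stop("field '", name, "': enum rule needs at least one allowed value",
         call. = FALSE)
  }
  oc <- lapply(ontology_constraints, function(c) {
    if (is.character(c)) c <- list(root = c)
    list(root = normalize_curie(c$root),
         include_root = isTRUE(c$include_root %||% TRUE))
  })
  if (identical(value_type, "ontology_id") && length(oc) == 0L) {
    stop("field '", name, "': ontology_id rule needs at least one ",
         "ontology constraint", call. = FALSE)
  }
  structure(
    list(name = trimws(name), description = description,
         requirement = requirement, value_type = value_type,
         allowed_values = as.character(allowed_values),
         valid_units = as.character(valid_units),
         ontology_constraints = oc,
         allow_multiple = isTRUE(allow_multiple)),
    class = "field_rule"
  )
}

#' Construct a rule section
#'
#' Sections group field rules; a section may carry an applicability
#' condition — a single attribute-equals-value predicate (e.g. assay type =
#' "RRBS") — in which case its rules apply only to records satisfying it.
#'
#' @param name Section name.
#' @param rules List of [field_rule()] objects.
#' @param condition Optional `list(attribute =, value =)` predicate.
#' @return An object of class `rule_section`.
#' @export
rule_section <- function(name, rules = list(), condition = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  for (r in rules) {
    if (!inherits(r, "field_rule")) stop("rules must be field_rule objects",
                                         call. = FALSE)
  }
  if (!is.null(condition)) {
    if (is.null(condition$attribute) || is.null(condition$value)) {
      stop("section condition needs 'attribute' and 'value'", call. = FALSE)
    }
    condition <- list(attribute = as.character(condition$attribute),
                      value = as.character(condition$value))
  }
  structure(list(name = name, condition = condition, rules = rules),
            class = "rule_section")
}

#' Construct a ruleset
#'
#' A ruleset is a versioned, tiered metadata checklist for one record
#' domain.  Versions are dotted `major.minor` numerals compared numerically
#' per component.  Field names must be unique across all sections.
#'
#' @param name Ruleset name.
#' @param version Dotted version text, e.g. `"3.5"`.
#' @param standard_tier `"full"` or `"legacy"`.
#' @param record_domain `"animal"`, `"specimen"` or `"experiment"`.  The
#'   `"animal"` domain is the combined animals-and-samples standard and also
#'   accepts specimen records.
#' @param sections List of [rule_section()] objects.
#' @return An object of class `ruleset`.
#' @export
ruleset <- function(name, version, standard_tier, record_domain,
                    sections = list()) {
  if (!grepl("^[0-9]+\\.[0-9]+$", version)) {
    stop("ruleset version must be 'major.minor' numerals, got '",
         version, "'", call. = FALSE)
  }
  if (!standard_tier %in% c("full", "legacy")) {
    stop("standard_tier must be 'full' or 'legacy'", call. = FALSE)
  }
  if (!record_domain %in% RECORD_DOMAINS) {
    stop("record_domain must be one of ",
         paste(RECORD_DOMAINS, collapse = ", "), call. = FALSE)
  }
  for (s in sections) {
    if (!inherits(s, "rule_section")) {
      stop("sections must be rule_section objects", call. = FALSE)
    }
  }
  rs <- structure(
    list(name = name, version = version, standard_tier = standard_tier,
         record_domain = record_domain, sections = sections),
    class = "ruleset"
  )
  nm <- vapply(ruleset_rules(rs), `[[`, character(1), "name")
  dup <- unique(nm[duplicated(tolower(nm))])
  if (length(dup)) {
    stop("duplicate field name(s) across sections: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (s in sections) {
    if (!is.null(s$condition) &&
        !tolower(s$condition$attribute) %in% tolower(nm)) {
      stop("section '", s$name, "' condition references undefined field '",
           s$condition$attribute, "'", call. = FALSE)
    }
  }
  rs
}

#' Flat list of a ruleset's field rules, in document order
#'
#' @param ruleset A [ruleset()].
#' @return List of `field_rule` objects (section order, then rule order).
#' @export
ruleset_rules <- function(ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  unlist(lapply(ruleset$sections, `[[`, "rules"), recursive = FALSE)
}

#' @export
print.ruleset <- function(x, ...) {
  n <- count_fields_by_tier(x)
  cat("<ruleset> ", x$name, " v", x$version, " (", x$standard_tier, ", ",
      x$record_domain, "): ", sum(n), " fields (",
      paste(names(n), n, sep = " ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Parse a version string into numeric components
#' @noRd
.parse_version <- function(v) as.integer(strsplit(v, ".", fixed = TRUE)[[1]])

#' Compare two dotted versions numerically (-1, 0, 1)
#' @noRd
.compare_versions <- function(a, b) {
  pa <- .parse_version(a); pb <- .parse_version(b)
  if (pa[1] != pb[1]) return(sign(pa[1] - pb[1]))
  sign(pa[2] - pb[2])
}

#' Load a ruleset from its JSON document
#'
#' The on-disk form is UTF-8 JSON:
#' `{name, version, standard_tier, record_domain,
#'   rule_groups: [{name, condition?, rules: [...]}]}`.
#' Loading is lossless: [write_ruleset()] of the result is semantically
#' identical to the input.
#'
#' @param path Path to a `.ruleset.json` file, or the JSON text itself.
#' @param paired_full Optional full-standard [ruleset()]: when given (for a
#'   legacy document), the legacy mandatory field names are checked to be a
#'   subset of the full ruleset's mandatory field names.
#' @return A [ruleset()].
#' @export
load_ruleset <- function(path, paired_full = NULL) {
  txt <- if (length(path) == 1L && file.exists(path)) {
    paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else path
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed ruleset JSON: ",
                                           conditionMessage(e), call. = FALSE))
  for (k in c("name", "version", "standard_tier", "record_domain")) {
    if (is.null(doc[[k]])) stop("ruleset document lacks '", k, "'",
                                call. = FALSE)
  }
  sections <- lapply(doc$rule_groups %||% list(), function(g) {
    rules <- lapply(g$rules %||% list(), function(r) {
      field_rule(
        name = r$name %||% "",
        requirement = r$requirement %||% "",
        value_type = r$value_type %||% "text",
        description = r$description %||% "",
        allowed_values = as.character(unlist(r$allowed_values %||% list())),
        valid_units = as.character(unlist(r$valid_units %||% list())),
        ontology_constraints = r$ontology_constraints %||% list(),
        allow_multiple = isTRUE(r$allow_multiple)
      )
    })
    rule_section(g$name %||% "", rules = rules, condition = g$condition)
  })
  rs <- ruleset(doc$name, doc$version, doc$standard_tier, doc$record_domain,
                sections)
  if (!is.null(paired_full)) .check_legacy_pair(paired_full, rs)
  rs
}

# legacy mandatory fields must be a subset of the paired full mandatory set
.check_legacy_pair <- function(full, legacy) {
  stopifnot(inherits(full, "ruleset"), inherits(legacy, "ruleset"))
  mand <- function(rs) {
    rules <- ruleset_rules(rs)
    tolower(vapply(rules, `[[`, character(1), "name")[
      vapply(rules, `[[`, character(1), "requirement") == "mandatory"])
  }
  extra <- setdiff(mand(legacy), mand(full))
  if (length(extra)) {
    stop("legacy ruleset requires field(s) the full standard does not: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a ruleset to its JSON document
#'
#' @param ruleset A [ruleset()].
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_ruleset <- function(ruleset, path = NULL) {
  stopifnot(inherits(ruleset, "ruleset"))
  doc <- list(
    name = ruleset$name, version = ruleset$version,
    standard_tier = ruleset$standard_tier,
    record_domain = ruleset$record_domain,
    rule_groups = lapply(ruleset$sections, function(s) {
      g <- list(name = s$name)
      if (!is.null(s$condition)) g$condition <- s$condition
      g$rules <- lapply(s$rules, function(r) {
        out <- list(name = r$name, description = r$description,
                    requirement = r$requirement, value_type = r$value_type)
        if (length(r$allowed_values)) out$allowed_values <- as.list(r$allowed_values)
        if (length(r$valid_units)) out$valid_units <- as.list(r$valid_units)
        if (length(r$ontology_constraints)) {
          out$ontology_constraints <- r$ontology_constraints
        }
        if (r$allow_multiple) out$allow_multiple <- TRUE
        out
      })
      g
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Count a ruleset's fields by requirement tier
#'
#' @param ruleset A [ruleset()].
#' @return Named integer vector `c(mandatory =, recommended =, optional =)`;
#'   every field rule is counted exactly once.
#' @export
count_fields_by_tier <- function(ruleset) {
  tiers <- vapply(ruleset_rules(ruleset), `[[`, character(1), "requirement")
  counts <- table(factor(tiers, levels = REQUIREMENT_TIERS))
  stats::setNames(as.integer(counts), REQUIREMENT_TIERS)
}

#' Diff two ruleset releases
#'
#' Reports field-level changes between two versions of a standard sharing a
#' record domain: fields added, fields removed, tier changes and constraint
#' changes (any change to value type, allowed values, units or ontology
#' constraints of a field present in both).
#'
#' @param old,new [ruleset()] objects with the same `record_domain`.
#' @return An object of class `ruleset_diff`: list with `added`, `removed`,
#'   `tier_changed` (data.frame name/old/new) and `constraint_changed`.
#' @export
diff_rulesets <- function(old, new) {
  stopifnot(inherits(old, "ruleset"), inherits(new, "ruleset"))
  if (!identical(old$record_domain, new$record_domain)) {
    stop("cannot diff rulesets for different record domains (",
         old$record_domain, " vs ", new$record_domain, ")", call. = FALSE)
  }
  index <- function(rs) {
    rules <- ruleset_rules(rs)
    stats::setNames(rules, tolower(vapply(rules, `[[`, character(1), "name")))
  }
  io <- index(old); inw <- index(new)
  added <- setdiff(names(inw), names(io))
  removed <- setdiff(names(io), names(inw))
  common <- intersect(names(io), names(inw))
  tier_changed <- data.frame(name = character(0), old = character(0),
                             new = character(0), stringsAsFactors = FALSE)
  constraint_changed <- character(0)
  for (nm in common) {
    a <- io[[nm]]; b <- inw[[nm]]
    if (!identical(a$requirement, b$requirement)) {
      tier_changed <- rbind(tier_changed, data.frame(
        name = b$name, old = a$requirement, new = b$requirement,
        stringsAsFactors = FALSE))
    }
    if (!identical(a$value_type, b$value_type) ||
        !identical(a$allowed_values, b$allowed_values) ||
        !identical(a$valid_units, b$valid_units) ||
        !identical(a$ontology_constraints, b$ontology_constraints)) {
      constraint_changed <- c(constraint_changed, b$name)
    }
  }
  structure(
    list(added = vapply(inw[added], `[[`, character(1), "name",
                        USE.NAMES = FALSE),
         removed = vapply(io[removed], `[[`, character(1), "name",
                          USE.NAMES = FALSE),
         tier_changed = tier_changed,
         constraint_changed = constraint_changed),
    class = "ruleset_diff"
  )
}

#' @export
print.ruleset_diff <- function(x, ...) {
  if (!length(x$added) && !length(x$removed) && !nrow(x$tier_changed) &&
      !length(x$constraint_changed)) {
    cat("no changes\n")
    return(invisible(x))
  }
  if (length(x$added)) cat("added:", paste(x$added, collapse = ", "), "\n")
  if (length(x$removed)) cat("removed:", paste(x$removed, collapse = ", "), "\n")
  if (nrow(x$tier_changed)) {
    for (i in seq_len(nrow(x$tier_changed))) {
      cat("tier: ", x$tier_changed$name[i], " ", x$tier_changed$old[i],
          " -> ", x$tier_changed$new[i], "\n", sep = "")
    }
  }
  if (length(x$constraint_changed)) {
    cat("constraints:", paste(x$constraint_changed, collapse = ", "), "\n")
  }
  invisible(x)
}

.rule_constraint_summary <- function(r) {
  parts <- character(0)
  if (length(r$allowed_values)) {
    parts <- c(parts, paste0("one of: ",
                             paste(r$allowed_values, collapse = ", ")))
  }
  if (length(r$ontology_constraints)) {
    roots <- vapply(r$ontology_constraints, `[[`, character(1), "root")
    parts <- c(parts, paste0("descendant of ",
                             paste(roots, collapse = " or ")))
  }
  paste(parts, collapse = "; ")
}

#' Render a ruleset as a table
#'
#' The human-readable rendering of the checklist: one row per field rule,
#' with columns section, field, requirement, value type, constraints and
#' units.  Ordering is deterministic (section order, then rule order), so
#' renderings are reproducible and the markdown/HTML/TSV forms carry
#' identical content.
#'
#' @param ruleset A [ruleset()].
#' @param format `"markdown"`, `"html"` or `"tsv"`.
#' @return A single string containing the rendered document.
#' @export
render_ruleset_table <- function(ruleset, format = c("markdown", "html", "tsv")) {
  format <- match.arg(format)
  header <- c("Section", "Field", "Requirement", "Type", "Constraints", "Units")
  rows <- list()
  for (s in ruleset$sections) {
    for (r in s$rules) {
      rows[[length(rows) + 1L]] <- c(
        s$name, r$name, r$requirement, r$value_type,
        .rule_constraint_summary(r), paste(r$valid_units, collapse = ", "))
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), ncol = length(header))
  switch(format,
    tsv = paste(c(paste(header, collapse = "\t"),
                  apply(m, 1, paste, collapse = "\t")), collapse = "\n"),
    markdown = {
      fmt_row <- function(x) paste0("| ", paste(x, collapse = " | "), " |")
      paste(c(fmt_row(header),
              fmt_row(rep("---", length(header))),
              if (nrow(m)) apply(m, 1, fmt_row)), collapse = "\n")
    },
    html = {
      esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
      }
      cells <- function(x, tag) paste0("<", tag, ">", esc(x), "</", tag, ">",
                                       collapse = "")
      body <- if (nrow(m)) paste0("<tr>", apply(m, 1, cells, tag = "td"),
                                  "</tr>", collapse = "\n") else ""
      paste0("<table>\n<tr>", cells(header, "th"), "</tr>\n", body,
             "\n</table>")
    })
}
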