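MISSING_VALUE_TERMS <- c("not applicable", "not collected", "not provided",
                         "restricted access")

#' Classify a value against the controlled missing-value vocabulary
#'
#' Absent values are recorded with exactly four controlled terms:
#' `"not applicable"` (the field does not apply), `"not collected"` (no
#' expectation it can ever be provided), `"not provided"` (may be added
#' later or obtained from the submitter) and `"restricted access"` (the
#' value exists but cannot be published).  Matching trims whitespace and
#' lower-cases; any other text is an ordinary value.
#'
#' @param value Character vector.
#' @return Character vector: the matched term, or `NA` where the value is
#'   not a missing-value term.
#' @examples
#' classify_missing_value("  Restricted Access ")
#' classify_missing_value("Texel")
#' @export
classify_missing_value <- function(value) {
  v <- tolower(trimws(as.character(value)))
  out <- ifelse(v %in% MISSING_VALUE_TERMS, v, NA_character_)
  out[is.na(value)] <- NA_character_
  out
}

#' The four controlled missing-value terms
#'
#' @return Character vector of length 4.
#' @export
missing_value_terms <- function() MISSING_VALUE_TERMS

#' Construct a record attribute
#'
#' One typed attribute of a record: a value, optional units, an optional
#' ontology term id and an optional preferred label.  The preferred label is
#' the submitter's own display name (e.g. a regional breed name) kept
#' alongside the ontology id, so programmatic linking through the hierarchy
#' is preserved without forcing a primary name on the depositor.
#'
#' @param field_name Field name.
#' @param value Attribute value text; must be non-empty or one of the four
#'   missing-value terms.
#' @param units Optional unit string.
#' @param term_id Optional ontology term id (any form; normalized to CURIE).
#' @param preferred_label Optional submitter display name.
#' @return An object of class `record_attribute`.
#' @export
record_attribute <- function(field_name, value, units = NA_character_,
                             term_id = NA_character_,
                             preferred_label = NA_character_) {
  value <- as.character(value)
  if (length(value) != 1L || is.na(value) ||
      (!nzchar(trimws(value)) && is.na(classify_missing_value(value)))) {
    stop("attribute '", field_name, "': value must be non-empty ",
         "or a controlled missing-value term", call. = FALSE)
  }
  structure(
    list(field_name = as.character(field_name), value = trimws(value),
         units = if (is.na(units) || !nzchar(units)) NA_character_
                 else as.character(units),
         term_id = if (is.na(term_id) || !nzchar(term_id)) NA_character_
                   else normalize_curie(term_id),
         preferred_label = if (is.na(preferred_label) ||
                               !nzchar(preferred_label)) NA_character_
                           else as.character(preferred_label)),
    class = "record_attribute"
  )
}

#' Construct a metadata record
#'
#' One animal, specimen or experiment with its attributes and
#' cross-references.  Specimens derive from animals (or other specimens),
#' experiments derive from specimens; animals may list parent animals via
#' `child_of`.  Contributors carry an ontology role term (a descendant of
#' EFO:0002012) so that responsibility and contact points are machine
#' readable.
#'
#' @param id Record identifier, unique within a submission.
#' @param record_domain `"animal"`, `"specimen"` or `"experiment"`.
#' @param attributes List of [record_attribute()] objects.
#' @param derived_from Optional id of the source record.
#' @param child_of Optional character vector of parent animal ids.
#' @param contributors Optional data.frame with columns `name` and `role`
#'   (role term CURIE).
#' @return An object of class `metadata_record`.
#' @export
metadata_record <- function(id, record_domain, attributes = list(),
                            derived_from = NA_character_,
                            child_of = character(0),
                            contributors = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(trimws(id))) {
    stop("record id must be a non-empty string", call. = FALSE)
  }
  if (!record_domain %in% RECORD_DOMAINS) {
    stop("record '", id, "': unknown record_domain '", record_domain, "'",
         call. = FALSE)
  }
  for (a in attributes) {
    if (!inherits(a, "record_attribute")) {
      stop("attributes must be record_attribute objects", call. = FALSE)
    }
  }
  if (!is.null(contributors)) {
    stopifnot(is.data.frame(contributors),
              all(c("name", "role") %in% names(contributors)))
    contributors$role <- normalize_curie(contributors$role)
  }
  structure(
    list(id = trimws(id), record_domain = record_domain,
         attributes = attributes,
         derived_from = if (is.na(derived_from) || !nzchar(derived_from))
           NA_character_ else trimws(derived_from),
         child_of = as.character(child_of),
         contributors = contributors),
    class = "metadata_record"
  )
}

#' @export
print.metadata_record <- function(x, ...) {
  cat("<record> ", x$id, " (", x$record_domain, "): ",
      length(x$attributes), " attributes",
      if (!is.na(x$derived_from)) paste0(", derived from ", x$derived_from),
      "\n", sep = "")
  invisible(x)
}

# case/whitespace-insensitive field-name key (spreadsheet headers vary)
.field_key <- function(x) gsub("[[:space:]]+", " ", tolower(trimws(x)))

#' Fetch a record's attributes for a field name
#' @noRd
.record_attrs <- function(record, field_name) {
  key <- .field_key(field_name)
  Filter(function(a) identical(.field_key(a$field_name), key),
         record$attributes)
}
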