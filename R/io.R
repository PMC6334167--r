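RESERVED_HEADERS <- c("Validation status", "Validation messages")
ID_HEADER <- "Record ID"
DOMAIN_HEADER <- "Record Domain"
DERIVED_HEADER <- "Derived From"
CHILD_HEADER <- "Child Of"

#' Template column layout for a ruleset
#'
#' Spreadsheet templates have a single header row derived from the ruleset
#' alone.  Ontology fields expand to a triplet — `<field>`,
#' `<field> Term Source REF`, `<field> Term Source ID` — and fields with
#' permitted units (or dates) add `<field> Unit`.  Four bookkeeping columns
#' (`Record ID`, `Record Domain`, `Derived From`, `Child Of`) lead.  The
#' expansion is invertible: readers fold the triplet back into one
#' attribute.
#'
#' @param ruleset A [ruleset()].
#' @return Character vector of ordered column headers.
#' @export
template_layout <- function(ruleset) {
  headers <- c(ID_HEADER, DOMAIN_HEADER, DERIVED_HEADER, CHILD_HEADER)
  for (r in ruleset_rules(ruleset)) {
    headers <- c(headers, r$name)
    if (identical(r$value_type, "ontology_id")) {
      headers <- c(headers, paste(r$name, "Term Source REF"),
                   paste(r$name, "Term Source ID"))
    }
    if (length(r$valid_units) || identical(r$value_type, "date")) {
      headers <- c(headers, paste(r$name, "Unit"))
    }
  }
  headers
}

.read_table <- function(file) {
  if (grepl("\\.xlsx$", file, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package; supply TSV instead",
           call. = FALSE)
    }
    df <- readxl::read_excel(file, col_types = "text")
    df <- as.data.frame(df, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- tryCatch(
      utils::read.delim(file, check.names = FALSE, colClasses = "character",
                        sep = "\t", quote = "", fileEncoding = "UTF-8",
                        na.strings = character(0)),
      error = function(e) stop("cannot read '", file, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  for (j in seq_along(df)) {
    df[[j]] <- trimws(ifelse(is.na(df[[j]]), "", as.character(df[[j]])))
  }
  # drop trailing all-empty rows
  keep <- apply(df, 1, function(row) any(nzchar(row)))
  df[keep, , drop = FALSE]
}

#' Read records from a spreadsheet template
#'
#' Accepts TSV (and `.xlsx` when readxl is installed) with the single
#' header row of [template_layout()].  Term Source REF/ID triplets fold into
#' one attribute with a normalized CURIE term id; `<field> Unit` columns
#' become attribute units; headers outside the layout become
#' additional-field attributes; annotation columns from a previous
#' validation round are ignored; cells are trimmed and empty trailing rows
#' skipped.
#'
#' @param file Path to a `.tsv`/`.txt` or `.xlsx` file.
#' @param ruleset The [ruleset()] the template was generated from.
#' @return List of [metadata_record()]s.
#' @export
read_records_spreadsheet <- function(file, ruleset) {
  df <- .read_table(file)
  headers <- names(df)
  hk <- .field_key(headers)
  id_col <- which(hk == .field_key(ID_HEADER))
  if (!length(id_col)) {
    stop("template lacks the '", ID_HEADER, "' column", call. = FALSE)
  }
  ids <- df[[id_col[1]]]
  dup <- unique(ids[duplicated(ids) & nzchar(ids)])
  if (length(dup)) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  # classify headers
  special <- .field_key(c(ID_HEADER, DOMAIN_HEADER, DERIVED_HEADER,
                          CHILD_HEADER, RESERVED_HEADERS))
  base_of <- function(h, suffix) {
    hit <- grepl(paste0("[[:space:]]", suffix, "$"), h, ignore.case = TRUE)
    ifelse(hit, sub(paste0("[[:space:]]+", suffix, "$"), "", h,
                    ignore.case = TRUE), NA_character_)
  }
  ref_base <- base_of(headers, "Term Source REF")
  tid_base <- base_of(headers, "Term Source ID")
  unit_base <- base_of(headers, "Unit")
  is_value_col <- is.na(ref_base) & is.na(tid_base) & is.na(unit_base) &
    !(hk %in% special)
  col_for <- function(base, kind_base) {
    i <- which(!is.na(kind_base) & .field_key(kind_base) == .field_key(base))
    if (length(i)) i[1] else NA_integer_
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- as.character(df[i, ])
    attrs <- list()
    for (j in which(is_value_col)) {
      if (!nzchar(row[j])) next
      tid <- NA_character_
      jt <- col_for(headers[j], tid_base)
      if (!is.na(jt) && nzchar(row[jt])) tid <- row[jt]
      ju <- col_for(headers[j], unit_base)
      units <- if (!is.na(ju) && nzchar(row[ju])) row[ju] else NA_character_
      attrs[[length(attrs) + 1L]] <- record_attribute(
        headers[j], row[j], units = units, term_id = tid)
    }
    dom <- {
      jd <- which(hk == .field_key(DOMAIN_HEADER))
      if (length(jd) && nzchar(row[jd[1]])) tolower(row[jd[1]])
      else ruleset$record_domain
    }
    jf <- which(hk == .field_key(DERIVED_HEADER))
    derived <- if (length(jf) && nzchar(row[jf[1]])) row[jf[1]]
               else NA_character_
    jc <- which(hk == .field_key(CHILD_HEADER))
    children <- if (length(jc) && nzchar(row[jc[1]])) {
      trimws(strsplit(row[jc[1]], ";", fixed = TRUE)[[1]])
    } else character(0)
    records[[i]] <- metadata_record(
      id = row[id_col[1]], record_domain = dom, attributes = attrs,
      derived_from = derived, child_of = children)
  }
  records
}

#' Write records to a spreadsheet template (TSV)
#'
#' The inverse of [read_records_spreadsheet()] for records whose attributes
#' fit the ruleset's [template_layout()]; attributes outside the layout get
#' their own trailing columns.  Output is UTF-8 TSV, deterministic.
#'
#' @param records List of [metadata_record()]s.
#' @param ruleset A [ruleset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_spreadsheet <- function(records, ruleset, path) {
  headers <- template_layout(ruleset)
  extra <- character(0)
  layout_keys <- .field_key(headers)
  for (r in records) {
    for (a in r$attributes) {
      if (!.field_key(a$field_name) %in% c(layout_keys, .field_key(extra))) {
        extra <- c(extra, a$field_name)
        if (!is.na(a$term_id)) {
          extra <- c(extra, paste(a$field_name, "Term Source REF"),
                     paste(a$field_name, "Term Source ID"))
        }
      }
    }
  }
  headers <- c(headers, extra)
  hk <- .field_key(headers)
  rows <- lapply(records, function(r) {
    row <- stats::setNames(rep("", length(headers)), headers)
    row[ID_HEADER] <- r$id
    row[DOMAIN_HEADER] <- r$record_domain
    row[DERIVED_HEADER] <- if (is.na(r$derived_from)) "" else r$derived_from
    row[CHILD_HEADER] <- paste(r$child_of, collapse = ";")
    for (a in r$attributes) {
      j <- which(hk == .field_key(a$field_name))[1]
      row[j] <- a$value
      if (!is.na(a$term_id)) {
        jr <- which(hk == .field_key(paste(a$field_name, "Term Source REF")))
        jt <- which(hk == .field_key(paste(a$field_name, "Term Source ID")))
        if (length(jr)) row[jr[1]] <- sub(":.*$", "", a$term_id)
        if (length(jt)) row[jt[1]] <- a$term_id
      }
      if (!is.na(a$units)) {
        ju <- which(hk == .field_key(paste(a$field_name, "Unit")))
        if (length(ju)) row[ju[1]] <- a$units
      }
    }
    row
  })
  lines <- c(paste(headers, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

.attr_to_list <- function(a) {
  out <- list(field = a$field_name, value = a$value)
  if (!is.na(a$units)) out$units <- a$units
  if (!is.na(a$term_id)) out$term_id <- a$term_id
  if (!is.na(a$preferred_label)) out$preferred_label <- a$preferred_label
  out
}

#' Read records from a JSON document
#'
#' The JSON form is an array of record objects:
#' `{"id", "record_domain", "derived_from"?, "child_of"?, "contributors"?,
#'   "attributes": [{"field", "value", "units"?, "term_id"?,
#'                   "preferred_label"?}]}`.
#' Reading the same logical content via JSON or spreadsheet yields equal
#' records.
#'
#' @param document Path to a JSON file, or JSON text.
#' @return List of [metadata_record()]s.
#' @export
read_records_json <- function(document) {
  txt <- if (length(document) == 1L && file.exists(document)) {
    paste(readLines(document, warn = FALSE, encoding = "UTF-8"),
          collapse = "\n")
  } else document
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed record JSON: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  lapply(doc, function(r) {
    if (is.null(r$id)) stop("record object lacks an 'id'", call. = FALSE)
    attrs <- lapply(r$attributes %||% list(), function(a) {
      record_attribute(a$field %||% a$field_name, a$value,
                       units = a$units %||% NA_character_,
                       term_id = a$term_id %||% NA_character_,
                       preferred_label = a$preferred_label %||% NA_character_)
    })
    contributors <- if (length(r$contributors %||% list())) {
      data.frame(
        name = vapply(r$contributors, function(c) c$name, character(1)),
        role = vapply(r$contributors, function(c) c$role, character(1)),
        stringsAsFactors = FALSE)
    } else NULL
    metadata_record(
      id = r$id, record_domain = r$record_domain %||% "animal",
      attributes = attrs,
      derived_from = r$derived_from %||% NA_character_,
      child_of = as.character(unlist(r$child_of %||% list())),
      contributors = contributors)
  })
}

#' Write records to the JSON document form
#'
#' @param records List of [metadata_record()]s.
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_records_json <- function(records, path = NULL) {
  doc <- lapply(records, function(r) {
    out <- list(id = r$id, record_domain = r$record_domain)
    if (!is.na(r$derived_from)) out$derived_from <- r$derived_from
    if (length(r$child_of)) out$child_of <- as.list(r$child_of)
    if (!is.null(r$contributors) && nrow(r$contributors)) {
      out$contributors <- lapply(seq_len(nrow(r$contributors)), function(i)
        list(name = r$contributors$name[i], role = r$contributors$role[i]))
    }
    out$attributes <- lapply(r$attributes, .attr_to_list)
    out
  })
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Write an annotated copy of a submitted template
#'
#' Reproduces the input spreadsheet with two appended columns per row —
#' `Validation status` (the record's overall result) and
#' `Validation messages` (the row's error and warning codes with their
#' messages, joined with `"; "`) — leaving the original cells untouched.
#' Readers ignore these reserved columns, so the annotated copy can be
#' corrected and resubmitted.  Output is TSV.
#'
#' @param file The submitted template (TSV or XLSX).
#' @param reports List of `record_report`s, one per data row, in row order.
#' @param path Output path; default adds `.annotated.tsv`.
#' @return `path`, invisibly.
#' @export
write_annotated_template <- function(file, reports,
                                     path = paste0(file, ".annotated.tsv")) {
  df <- .read_table(file)
  if (nrow(df) != length(reports)) {
    stop("report/row count mismatch: ", nrow(df), " data rows vs ",
         length(reports), " reports", call. = FALSE)
  }
  df <- df[, !names(df) %in% RESERVED_HEADERS, drop = FALSE]
  status <- vapply(reports, `[[`, character(1), "overall")
  messages <- vapply(reports, function(r) {
    sel <- which(r$outcomes$status %in% c("error", "warning"))
    if (!length(sel)) return("")
    paste(paste0(r$outcomes$code[sel], ": ", r$outcomes$field_name[sel]),
          collapse = "; ")
  }, character(1))
  df[["Validation status"]] <- status
  df[["Validation messages"]] <- messages
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
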