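#' Normalize an ontology term identifier to CURIE form
#'
#' Ontology terms circulate in three spellings: full IRIs
#' (`http://purl.obolibrary.org/obo/PATO_0000461`,
#' `http://www.ebi.ac.uk/efo/EFO_0000408`), underscore short forms
#' (`PATO_0000461`) and CURIEs (`PATO:0000461`).  All three normalize to the
#' CURIE `PREFIX:LOCAL`, which is the canonical key used throughout the
#' package.  Normalization is idempotent.
#'
#' @param id Character vector of term identifiers in any of the three forms.
#' @return Character vector of CURIEs; `NA` entries stay `NA`.  Strings that
#'   cannot be interpreted as a term identifier are returned trimmed but
#'   otherwise unchanged (callers decide whether that is an error).
#' @examples
#' normalize_curie("http://purl.obolibrary.org/obo/PATO_0000461")
#' normalize_curie(c("EFO_0000408", "LBO:0001036"))
#' @export
normalize_curie <- function(id) {
  if (length(id) == 0L) return(character(0))
  out <- trimws(as.character(id))
  live <- !is.na(out) & nzchar(out)
  strip_iri <- function(x) {
    # keep the final path/fragment segment of an IRI
    x <- sub("^https?://[^ ]*[/#]", "", x)
    x
  }
  out[live] <- vapply(out[live], function(x) {
    if (grepl("^https?://", x)) x <- strip_iri(x)
    if (grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9_.-]+$", x)) return(x)
    if (grepl("^[A-Za-z][A-Za-z0-9]*_[A-Za-z0-9.-]+$", x)) {
      return(sub("_", ":", x))
    }
    x
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Test whether a string is a well-formed CURIE
#'
#' @param id Character vector.
#' @return Logical vector: `TRUE` where the entry matches `PREFIX:LOCAL`.
#' @export
is_curie <- function(id) {
  !is.na(id) & grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9_.-]+$", id)
}

#' Expand a CURIE to an OBO-style IRI
#'
#' Used when writing BioSamples-style submission documents, whose
#' `ontologyTerms` entries carry full IRIs.  EFO terms live under the EBI
#' namespace; everything else under the OBO PURL namespace.
#'
#' @param curie Character vector of CURIEs.
#' @return Character vector of IRIs.
#' @export
curie_to_iri <- function(curie) {
  curie <- normalize_curie(curie)
  vapply(curie, function(x) {
    if (is.na(x) || !is_curie(x)) return(NA_character_)
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    local <- paste0(parts[1], "_", parts[2])
    if (identical(parts[1], "EFO")) {
      paste0("http://www.ebi.ac.uk/efo/", local)
    } else {
      paste0("http://purl.obolibrary.org/obo/", local)
    }
  }, character(1), USE.NAMES = FALSE)
}
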