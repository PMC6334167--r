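#' Crossbreed nomenclature
#'
#' Crossbred animals are recorded with a species-specific "crossbreed"
#' ontology term (e.g. LBO:0001036 for cattle, LBO:0001038 for goat) plus a
#' custom breed name following the grammar
#'
#' ```
#' cross  := parent " sire x " parent " dam"
#' parent := breed-name | "(" cross ")" | "unknown"
#' ```
#'
#' The sire is always listed first.  Both the multiplication sign U+00D7 and
#' a plain ASCII `x` are accepted as the separator on input; the canonical
#' serialization uses U+00D7.  Parents that are themselves crossbred are
#' parenthesised; a parent of unknown breed is the literal token `unknown`.
#'
#' @name crossbreed-grammar
NULL

.breed_leaf <- function(name, term_id = NA_character_) {
  structure(list(kind = "leaf", name = name, term_id = term_id),
            class = "breed_descriptor")
}

.breed_cross <- function(sire, dam) {
  stopifnot(inherits(sire, "breed_descriptor"),
            inherits(dam, "breed_descriptor"))
  structure(list(kind = "cross", sire = sire, dam = dam),
            class = "breed_descriptor")
}

# paren depth at each character of s (before consuming that character)
.paren_depth <- function(chars) {
  depth <- integer(length(chars))
  d <- 0L
  for (i in seq_along(chars)) {
    depth[i] <- d
    if (chars[i] == "(") d <- d + 1L
    if (chars[i] == ")") {
      d <- d - 1L
      if (d < 0L) stop("unbalanced ')' at position ", i, call. = FALSE)
    }
  }
  if (d != 0L) stop("unbalanced '(' in breed name", call. = FALSE)
  depth
}

.SIRE_SEP <- "(^|[[:space:]]+)sire[[:space:]]+(×|x)[[:space:]]+"

#' Parse a crossbreed name
#'
#' Parses `"breed sire x breed dam"` text (see [crossbreed-grammar]) into a
#' tree of purebred leaves and sire/dam cross nodes.  Text without the
#' sire/dam markers is rejected — a plain purebred name is not a cross.
#'
#' @param text Breed name text.
#' @return A `breed_descriptor` cross node.
#' @examples
#' d <- parse_crossbreed_name("Texel sire × Scottish Blackface dam")
#' format(d)
#' @export
parse_crossbreed_name <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    stop("empty breed name", call. = FALSE)
  }
  .parse_cross(trimws(text))
}

.parse_cross <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- .paren_depth(chars)
  m <- gregexpr(.SIRE_SEP, s)[[1]]
  starts <- as.integer(m)
  if (starts[1] == -1L) {
    stop("no 'sire'/'dam' markers found in '", s,
         "': not a crossbreed name", call. = FALSE)
  }
  lens <- attr(m, "match.length")
  top <- which(depth[starts] == 0L)
  if (length(top) == 0L) {
    stop("no top-level 'sire' marker in '", s, "'", call. = FALSE)
  }
  if (length(top) > 1L) {
    stop("ambiguous crossbreed name '", s, "': multiple top-level 'sire' ",
         "markers at positions ", paste(starts[top], collapse = ", "),
         call. = FALSE)
  }
  i <- top[1]
  sire_txt <- substr(s, 1L, starts[i] - 1L)
  rest <- substr(s, starts[i] + lens[i], nchar(s))
  dm <- regexpr("[[:space:]]+dam$", rest)
  if (dm == -1L) {
    stop("missing trailing 'dam' marker in '", s, "' (position ",
         nchar(s), ")", call. = FALSE)
  }
  dam_txt <- substr(rest, 1L, as.integer(dm) - 1L)
  .breed_cross(.parse_parent(sire_txt), .parse_parent(dam_txt))
}

.parse_parent <- function(t) {
  t <- trimws(t)
  if (!nzchar(t)) stop("empty parent in crossbreed name", call. = FALSE)
  if (tolower(t) == "unknown") return(.breed_leaf("unknown"))
  if (startsWith(t, "(")) {
    chars <- strsplit(t, "")[[1]]
    depth <- .paren_depth(chars)
    # the opening paren must wrap the whole parent
    closes <- which(chars == ")" & depth == 1L)
    if (!endsWith(t, ")") || closes[length(closes)] != nchar(t)) {
      stop("mis-parenthesised parent '", t, "'", call. = FALSE)
    }
    return(.parse_cross(substr(t, 2L, nchar(t) - 1L)))
  }
  if (grepl("\\bsire\\b|\\bdam\\b|×", t)) {
    stop("parent '", t, "' looks like an unparenthesised cross",
         call. = FALSE)
  }
  .breed_leaf(t)
}

#' @export
format.breed_descriptor <- function(x, ...) {
  wrap <- function(d) {
    if (d$kind == "cross") paste0("(", format(d), ")") else format(d)
  }
  if (x$kind == "leaf") return(x$name)
  paste0(wrap(x$sire), " sire × ", wrap(x$dam), " dam")
}

#' @export
print.breed_descriptor <- function(x, ...) {
  cat(if (x$kind == "cross") "<crossbreed> " else "<purebred> ",
      format(x), "\n", sep = "")
  invisible(x)
}

#' Does a breed name use the crossbreed markers?
#'
#' Distinguishes text that attempts the crossbreed grammar (and must parse)
#' from a plain purebred name.
#'
#' @param text Breed name text.
#' @return Single logical.
#' @export
is_crossbreed_name <- function(text) {
  grepl("\\bsire\\b|\\bdam\\b|×", text)
}
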