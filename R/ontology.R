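#' Construct an ontology graph
#'
#' An `ontology_graph` is an in-memory DAG of terms connected by is-a edges.
#' It backs the hierarchy-aware validation rules: a field constrained to a
#' root term accepts any descendant of that root.  Only is-a edges are
#' modelled; multiple parents are allowed.
#'
#' @param terms A data.frame-like list of terms, or a list of per-term lists,
#'   each with `id`, `label`, optional `synonyms` (character) and optional
#'   `parents` (character, any identifier form).
#' @return An object of class `ontology_graph` with components `terms`
#'   (named list of term records keyed by CURIE) and `roots` (character).
#' @export
ontology_graph <- function(terms) {
  if (is.data.frame(terms)) {
    terms <- lapply(seq_len(nrow(terms)), function(i) as.list(terms[i, ]))
  }
  nodes <- list()
  for (t in terms) {
    id <- normalize_curie(t$id)
    if (length(id) != 1L || !is_curie(id)) {
      stop("ontology term id is not a valid identifier: ",
           deparse(t$id), call. = FALSE)
    }
    label <- as.character(t$label %||% "")
    if (!nzchar(label)) {
      stop("ontology term ", id, " has an empty label", call. = FALSE)
    }
    if (id %in% names(nodes)) {
      stop("duplicate ontology term id: ", id, call. = FALSE)
    }
    nodes[[id]] <- list(
      id = id,
      label = label,
      synonyms = as.character(unlist(t$synonyms %||% character(0))),
      parents = unique(normalize_curie(
        as.character(unlist(t$parents %||% character(0)))))
    )
  }
  for (n in nodes) {
    missing <- setdiff(n$parents, names(nodes))
    if (length(missing)) {
      stop("term ", n$id, " references unknown parent(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  g <- structure(
    list(terms = nodes,
         roots = names(nodes)[vapply(nodes, function(n)
           length(n$parents) == 0L, logical(1))]),
    class = "ontology_graph"
  )
  cyc <- .find_cycle(g)
  if (!is.null(cyc)) {
    stop("is-a cycle detected: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  g$ancestors <- .closure(g)
  g
}

# ancestor closure for every term, computed once at construction
.closure <- function(graph) {
  anc <- list()
  visit <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    parents <- graph$terms[[id]]$parents
    out <- parents
    for (p in parents) out <- c(out, visit(p))
    out <- unique(out)
    anc[[id]] <<- out
    out
  }
  for (id in names(graph$terms)) visit(id)
  anc
}

# depth-first search for a parent-edge cycle; returns one cycle or NULL
.find_cycle <- function(graph) {
  state <- new.env(parent = emptyenv())
  for (id in names(graph$terms)) assign(id, 0L, envir = state)  # 0 new 1 open 2 done
  path <- character(0)
  visit <- function(id) {
    s <- get(id, envir = state)
    if (s == 1L) {
      i <- match(id, path)
      return(c(path[i:length(path)], id))
    }
    if (s == 2L) return(NULL)
    assign(id, 1L, envir = state)
    path[[length(path) + 1L]] <<- id
    for (p in graph$terms[[id]]$parents) {
      cyc <- visit(p)
      if (!is.null(cyc)) return(cyc)
    }
    path <<- path[-length(path)]
    assign(id, 2L, envir = state)
    NULL
  }
  for (id in names(graph$terms)) {
    cyc <- visit(id)
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$terms), " terms, ",
      length(x$roots), " roots\n", sep = "")
  invisible(x)
}

#' Load an ontology graph from a JSON graph or OBO subset file
#'
#' Two on-disk forms are read: a JSON graph
#' `{"terms": [{"id", "label", "synonyms", "parents"}, ...]}` and a subset of
#' the OBO flat-file format (`[Term]` stanzas with `id`, `name`, `synonym`
#' and `is_a` tags).  Identifiers in IRI, underscore or CURIE form all
#' normalize to CURIEs.
#'
#' @param path Path to a `.json` or `.obo` file, or a JSON string.
#' @return An [ontology_graph()].
#' @export
load_ontology <- function(path) {
  if (length(path) == 1L && grepl("\\.obo$", path)) {
    return(ontology_graph(.parse_obo(readLines(path, warn = FALSE))))
  }
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(doc$terms)) {
    stop("ontology JSON document lacks a 'terms' array", call. = FALSE)
  }
  ontology_graph(doc$terms)
}

.parse_obo <- function(lines) {
  terms <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
  for (ln in c(lines, "[Term]")) {
    ln <- trimws(ln)
    if (identical(ln, "[Term]")) {
      flush(); cur <- list(synonyms = character(0), parents = character(0))
    } else if (is.null(cur) || !nzchar(ln) || grepl("^\\[", ln)) {
      if (grepl("^\\[", ln) && !identical(ln, "[Term]")) { flush(); cur <- NULL }
    } else if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^name:", ln)) {
      cur$label <- trimws(sub("^name:", "", ln))
    } else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- trimws(sub("!.*$", "", tgt))
      cur$parents <- c(cur$parents, tgt)
    }
  }
  terms
}

#' Serialize an ontology graph to its JSON graph form
#'
#' @param graph An [ontology_graph()].
#' @param path Optional output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
write_ontology <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  terms <- unname(lapply(graph$terms, function(t) list(
    id = t$id, label = t$label,
    synonyms = as.list(t$synonyms), parents = as.list(t$parents))))
  txt <- jsonlite::toJSON(list(terms = terms), auto_unbox = TRUE,
                          pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

.check_term <- function(graph, id) {
  id <- normalize_curie(id)
  if (!id %in% names(graph$terms)) {
    stop("unknown ontology term: ", id, call. = FALSE)
  }
  id
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by following is-a edges towards the roots,
#' excluding `term` itself.  A root term has no ancestors.
#'
#' @param graph An [ontology_graph()].
#' @param term Term identifier (any form).
#' @return Character vector of CURIEs (unordered, no duplicates).
#' @export
term_ancestors <- function(graph, term) {
  term <- .check_term(graph, term)
  if (!is.null(graph$ancestors)) {
    return(graph$ancestors[[term]] %||% character(0))
  }
  seen <- character(0)
  frontier <- graph$terms[[term]]$parents
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(id)
      graph$terms[[id]]$parents), use.names = FALSE))
  }
  seen
}

#' Is one term a descendant of another?
#'
#' Hierarchy rules accept any term below a constraint root: `term` satisfies
#' the rule when `ancestor` is reachable from it via is-a edges.  With
#' `include_self = TRUE` (the default used by validation) the root itself is
#' also accepted.
#'
#' @param graph An [ontology_graph()].
#' @param term,ancestor Term identifiers (any form).
#' @param include_self Accept `term == ancestor`?
#' @return Single logical.
#' @export
is_descendant <- function(graph, term, ancestor, include_self = FALSE) {
  term <- .check_term(graph, term)
  ancestor <- .check_term(graph, ancestor)
  if (include_self && identical(term, ancestor)) return(TRUE)
  ancestor %in% term_ancestors(graph, term)
}

.normalize_text <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", x)
}

#' Match free text against term labels and synonyms
#'
#' A local, deterministic stand-in for remote curation services: depositors'
#' free-text values are matched against the graph's labels and synonyms.
#' Exact label matches rank first, then synonym matches, then matches after
#' case/punctuation normalization.  Ties within a rank are ordered
#' lexicographically by CURIE.
#'
#' @param graph An [ontology_graph()].
#' @param text A single free-text string.
#' @return A data.frame with columns `id` and `match_kind`
#'   (`exact_label`, `synonym`, `normalized`); zero rows when nothing
#'   matches.
#' @export
match_term_label <- function(graph, text) {
  empty <- data.frame(id = character(0), match_kind = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty)
  text <- trimws(text)
  hits <- list()
  add <- function(id, kind) hits[[length(hits) + 1L]] <<- c(id = id, match_kind = kind)
  norm_q <- .normalize_text(text)
  for (t in graph$terms) {
    if (identical(t$label, text)) {
      add(t$id, "exact_label")
    } else if (text %in% t$synonyms) {
      add(t$id, "synonym")
    } else if (identical(.normalize_text(t$label), norm_q) ||
               norm_q %in% .normalize_text(t$synonyms)) {
      add(t$id, "normalized")
    }
  }
  if (!length(hits)) return(empty)
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  rank <- match(df$match_kind, c("exact_label", "synonym", "normalized"))
  df <- df[order(rank, df$id), , drop = FALSE]
  df <- df[!duplicated(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
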