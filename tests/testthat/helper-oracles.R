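# Shared fixtures and independent oracles used across the suite.

FIXTURE_GRAPH <- build_fixture_ontology()
FIXTURE_RULESETS <- faang_rulesets()

# --- graph fixtures ------------------------------------------------------

chain_graph <- function() {
  # A -> B -> C (A is the most specific term)
  ontology_graph(list(
    list(id = "T:C", label = "C"),
    list(id = "T:B", label = "B", parents = "T:C"),
    list(id = "T:A", label = "A", parents = "T:B")
  ))
}

diamond_graph <- function() {
  # A -> B, A -> C, B -> D, C -> D
  ontology_graph(list(
    list(id = "T:D", label = "D"),
    list(id = "T:B", label = "B", parents = "T:D"),
    list(id = "T:C", label = "C", parents = "T:D"),
    list(id = "T:A", label = "A", parents = c("T:B", "T:C"))
  ))
}

# Random DAG: parents are always earlier-numbered terms, so acyclicity is
# guaranteed by construction.  Returns the graph plus its id vector.
random_dag <- function(n_terms) {
  terms <- vector("list", n_terms)
  ids <- sprintf("RND:%04d", seq_len(n_terms))
  for (i in seq_len(n_terms)) {
    k <- if (i == 1L) 0L else sample(0:min(3L, i - 1L), 1L)
    parents <- if (k > 0L) sample(ids[seq_len(i - 1L)], k) else character(0)
    terms[[i]] <- list(id = ids[i], label = paste("term", i),
                       parents = parents)
  }
  list(graph = ontology_graph(terms), ids = ids)
}

# Brute-force reachability oracle: boolean adjacency matrix iterated to its
# transitive-closure fixpoint — an independent route to the same relation.
closure_matrix <- function(graph, ids) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) adj[id, graph$terms[[id]]$parents] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% adj > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# --- naive validation oracle ---------------------------------------------

# Straight-line re-implementation of the requirement-tier x missing-value
# decision table and value contracts, counting errors the obvious way.
# Deliberately independent of the package's outcome machinery.
naive_descendant <- function(graph, term, root) {
  for (p in graph$terms[[term]]$parents) {
    if (p == root || naive_descendant(graph, p, root)) return(TRUE)
  }
  FALSE
}

naive_key <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

naive_cross_shape_ok <- function(value) {
  grepl("[[:space:]]sire[[:space:]]+(×|x)[[:space:]]", value) &&
    grepl("[[:space:]]dam$", trimws(value))
}

naive_error_count <- function(record, ruleset, graph) {
  mv <- c("not applicable", "not collected", "not provided",
          "restricted access")
  errors <- 0L
  rules <- list()
  for (section in ruleset$sections) {
    applies <- TRUE
    if (!is.null(section$condition)) {
      applies <- FALSE
      for (a in record$attributes) {
        if (naive_key(a$field_name) == naive_key(section$condition$attribute) &&
            trimws(a$value) == section$condition$value) {
          applies <- TRUE
        }
      }
    }
    if (applies) rules <- c(rules, section$rules)
  }
  for (rule in rules) {
    hits <- list()
    for (a in record$attributes) {
      if (naive_key(a$field_name) == naive_key(rule$name)) {
        hits <- c(hits, list(a))
      }
    }
    if (!length(hits)) {
      if (rule$requirement == "mandatory") errors <- errors + 1L
      next
    }
    if (length(hits) > 1L && !rule$allow_multiple) errors <- errors + 1L
    for (a in hits) {
      v <- tolower(trimws(a$value))
      if (v %in% mv) {
        if (rule$requirement == "mandatory" && v != "restricted access") {
          errors <- errors + 1L
        }
        next
      }
      if (length(rule$valid_units) &&
          (is.na(a$units) || !a$units %in% rule$valid_units)) {
        errors <- errors + 1L
      }
      if (rule$value_type == "enum" && !a$value %in% rule$allowed_values) {
        errors <- errors + 1L
      }
      if (rule$value_type == "number" &&
          is.na(suppressWarnings(as.numeric(a$value)))) {
        errors <- errors + 1L
      }
      if (rule$value_type == "date") {
        fmt <- if (!is.na(a$units)) a$units else "YYYY-MM-DD"
        pat <- c("YYYY-MM-DD" = "^\\d{4}-\\d{2}-\\d{2}$",
                 "YYYY-MM" = "^\\d{4}-\\d{2}$", "YYYY" = "^\\d{4}$")[fmt]
        if (is.na(pat) || !grepl(pat, a$value)) errors <- errors + 1L
      }
      if (rule$value_type == "uri" && !grepl("^(https?|ftp)://", a$value)) {
        errors <- errors + 1L
      }
      if (rule$value_type == "doi" && !grepl("10\\.\\d{4,}/", a$value)) {
        errors <- errors + 1L
      }
      if (rule$value_type == "ontology_id") {
        if (is.na(a$term_id) || !a$term_id %in% names(graph$terms)) {
          errors <- errors + 1L
        } else {
          ok <- FALSE
          for (con in rule$ontology_constraints) {
            if ((con$include_root && a$term_id == con$root) ||
                (con$root %in% names(graph$terms) &&
                 naive_descendant(graph, a$term_id, con$root))) {
              ok <- TRUE
            }
          }
          if (!ok) errors <- errors + 1L
        }
      }
    }
    if (naive_key(rule$name) == "breed") {
      species <- NA_character_
      for (a in record$attributes) {
        if (naive_key(a$field_name) == "organism") species <- a$term_id
      }
      for (a in hits) {
        v <- tolower(trimws(a$value))
        if (v %in% mv) next
        if (grepl("\\bsire\\b|\\bdam\\b|×", a$value)) {
          if (!naive_cross_shape_ok(a$value)) {
            errors <- errors + 1L
          } else if (!is.na(species) && species %in% names(crossbreed_terms()) &&
                     (is.na(a$term_id) ||
                      a$term_id != crossbreed_terms()[[species]])) {
            errors <- errors + 1L
          }
        } else {
          if (is.na(a$term_id) || !grepl("^LBO:", a$term_id) ||
              !a$term_id %in% names(graph$terms)) {
            errors <- errors + 1L
          }
        }
      }
    }
  }
  if (!is.null(record$contributors) && nrow(record$contributors)) {
    for (i in seq_len(nrow(record$contributors))) {
      role <- record$contributors$role[i]
      if (is.na(role) || !role %in% names(graph$terms) ||
          !naive_descendant(graph, role, "EFO:0002012")) {
        errors <- errors + 1L
      }
    }
  }
  errors
}

# --- small record builders ------------------------------------------------

valid_animal_record <- function(id = "A1", seed = 99) {
  sub <- generate_submission(1, defect_spec(),
                             rulesets = FIXTURE_RULESETS,
                             graph = FIXTURE_GRAPH, seed = seed,
                             with_contributors = FALSE)
  r <- sub$records[[1]]
  r$id <- id
  r$child_of <- character(0)
  r
}

report_error_codes <- function(report) {
  sort(unique(report$outcomes$code[report$outcomes$status == "error"]))
}
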