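# Minimal OBO-style ontology reader and DAG utilities. Only [Term] stanzas
# with id:, is_a: and relationship: part_of are interpreted; that subset is
# the contract (full OBO 1.4 parsing is out of scope).

#' Read an ontology DAG from an OBO-lite file
#'
#' Parses `[Term]` stanzas with `id:`, `is_a:` and `relationship: part_of`
#' lines. Terms referenced only as parents are added as (rootward) terms.
#' The graph must be acyclic; a cycle raises an error listing one offending
#' cycle.
#'
#' @param path Path to the OBO file.
#' @return Object of class `dynafic_ontology`: a list with `terms`
#'   (character vector), `parents` (named list; each element a named
#'   character vector, names = parent term ids, values = relation,
#'   `"is_a"` or `"part_of"`), `roots`, and `depth` (named numeric,
#'   longest path to a root, roots at 0).
#' @export
read_ontology <- function(path) {
  lines <- readLines(path)
  parents <- list()
  terms <- character(0)
  cur <- NULL
  flush <- function(id, rels) {
    if (is.null(id)) return()
    terms <<- c(terms, id)
    parents[[id]] <<- rels
  }
  rels <- character(0)
  in_term <- FALSE
  obsolete <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      if (in_term && !obsolete) flush(cur, rels)
      in_term <- identical(ln, "[Term]")
      cur <- NULL; rels <- character(0); obsolete <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    } else if (in_term && grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      r <- stats::setNames("is_a", tgt)
      rels <- c(rels, r)
    } else if (in_term && grepl("^relationship:\\s*part_of", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      r <- stats::setNames("part_of", tgt)
      rels <- c(rels, r)
    }
  }
  if (in_term && !obsolete) flush(cur, rels)
  if (!length(terms)) stop(path, ": no [Term] stanzas found")
  # parents referenced but never declared become root terms
  referenced <- unique(unlist(lapply(parents, names), use.names = FALSE))
  extra <- setdiff(referenced, terms)
  terms <- c(terms, extra)
  for (t in extra) parents[[t]] <- character(0)
  for (t in terms) if (is.null(parents[[t]])) parents[[t]] <- character(0)
  dag <- structure(list(terms = terms, parents = parents[terms]),
                   class = "dynafic_ontology")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology is cyclic: ", paste(cyc, collapse = " -> "))
  }
  dag$roots <- terms[vapply(dag$parents, length, 1L) == 0L]
  dag$depth <- ontology_depths(dag)
  dag
}

#' Build an ontology object from parent relations in memory
#'
#' Programmatic counterpart of [read_ontology()], used by the synthetic-data
#' generators and in tests.
#'
#' @param parents Named list; element `t` is a named character vector whose
#'   names are the parents of `t` and whose values are the relations
#'   (`"is_a"` or `"part_of"`). Terms with no parents map to
#'   `character(0)`.
#' @return A `dynafic_ontology` object.
#' @export
ontology_from_parents <- function(parents) {
  terms <- union(names(parents),
                 unlist(lapply(parents, names), use.names = FALSE))
  for (t in setdiff(terms, names(parents))) parents[[t]] <- character(0)
  dag <- structure(list(terms = terms, parents = parents[terms]),
                   class = "dynafic_ontology")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology is cyclic: ", paste(cyc, collapse = " -> "))
  }
  dag$roots <- terms[vapply(dag$parents, length, 1L) == 0L]
  dag$depth <- ontology_depths(dag)
  dag
}

# Depth-first search for a directed cycle along child -> parent links.
# Returns one cycle as a character vector, or NULL.
find_cycle <- function(dag) {
  state <- stats::setNames(rep(0L, length(dag$terms)), dag$terms)
  stack <- character(0)
  found <- NULL
  visit <- function(t) {
    if (!is.null(found)) return()
    state[t] <<- 1L
    stack <<- c(stack, t)
    for (p in names(dag$parents[[t]])) {
      if (state[p] == 1L) {
        i <- match(p, stack)
        found <<- c(stack[i:length(stack)], p)
        return()
      }
      if (state[p] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    state[t] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (t in dag$terms) if (state[t] == 0L) visit(t)
  found
}

# Longest path from each term down to any root (roots have depth 0),
# computed by memoized recursion over parent links.
ontology_depths <- function(dag) {
  depth <- stats::setNames(rep(NA_real_, length(dag$terms)), dag$terms)
  get_depth <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    ps <- names(dag$parents[[t]])
    d <- if (!length(ps)) 0 else 1 + max(vapply(ps, get_depth, 0))
    depth[[t]] <<- d
    d
  }
  for (t in dag$terms) get_depth(t)
  depth
}

#' Ancestors of a term (inclusive)
#'
#' @param term Term identifier.
#' @param dag A `dynafic_ontology`.
#' @return Character vector of `term` and all terms reachable via parent
#'   links.
#' @export
term_ancestors <- function(term, dag) {
  if (!term %in% dag$terms) stop("unknown ontology term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(dag$parents[frontier], names), use.names = FALSE)),
      seen)
  }
  seen
}

#' @export
print.dynafic_ontology <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d root(s), max depth %d\n",
              length(x$terms), length(x$roots), max(x$depth)))
  invisible(x)
}
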