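# GO semantic similarity: Wang's graph-based measure plus the best-match
# average (BMA) combination over gene annotation sets. Contribution factors
# default to the standard 0.8 (is_a) and 0.6 (part_of).

# S-values of `term` over its ancestor set: S(term) = 1 and, walking
# rootward, S(t) = max over children c of t on paths to `term` of
# contrib(relation(c -> t)) * S(c). Computed by relaxation to a fixed
# point, which terminates because the DAG is acyclic.
term_svalues <- function(term, dag, contrib = c(is_a = 0.8, part_of = 0.6)) {
  anc <- term_ancestors(term, dag)
  s <- stats::setNames(rep(0, length(anc)), anc)
  s[term] <- 1
  repeat {
    changed <- FALSE
    for (child in anc) {
      rels <- dag$parents[[child]]
      for (i in seq_along(rels)) {
        p <- names(rels)[i]
        cand <- contrib[[rels[[i]]]] * s[[child]]
        if (cand > s[[p]]) {
          s[[p]] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' Each term contributes S-values to its ancestors (its own S-value is 1;
#' an ancestor's S-value is the maximum product of contribution factors
#' along descending paths). The similarity is the sum of both terms'
#' S-values over their shared ancestors, divided by the sum of all their
#' S-values. Symmetric, bounded in [0, 1], and 1 for identical terms.
#'
#' @param a,b Term identifiers present in `dag`.
#' @param dag A `dynafic_ontology`.
#' @param contrib Named contribution factors per relation, each in (0, 1).
#' @return Similarity in [0, 1].
#' @export
wang_term_similarity <- function(a, b, dag,
                                 contrib = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(contrib > 0), all(contrib < 1))
  sa <- term_svalues(a, dag, contrib)
  sb <- term_svalues(b, dag, contrib)
  wang_from_svalues(sa, sb)
}

wang_from_svalues <- function(sa, sb) {
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

#' Pairwise Wang similarity matrix for a set of terms
#'
#' S-value vectors are computed once per term, so building the full matrix
#' costs one ancestor traversal per term plus one intersection per pair.
#'
#' @param terms Character vector of term ids.
#' @inheritParams wang_term_similarity
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
term_similarity_matrix <- function(terms, dag,
                                   contrib = c(is_a = 0.8, part_of = 0.6)) {
  terms <- unique(terms)
  sv <- lapply(terms, term_svalues, dag = dag, contrib = contrib)
  n <- length(terms)
  M <- diag(1, n)
  dimnames(M) <- list(terms, terms)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        M[i, j] <- M[j, i] <- wang_from_svalues(sv[[i]], sv[[j]])
      }
    }
  }
  M
}

#' Functional similarity between two genes (best-match average)
#'
#' Combines the pairwise term similarities of the two genes' annotation
#' sets with the best-match average: the mean of (a) the average over rows
#' of the row maxima and (b) the average over columns of the column maxima
#' of the term-similarity matrix.
#'
#' @param g1,g2 Gene symbols.
#' @param annotations Named list gene -> character vector of term ids.
#' @param dag A `dynafic_ontology`.
#' @param term_sim Optional precomputed term-similarity matrix covering all
#'   annotation terms (from [term_similarity_matrix()]).
#' @inheritParams wang_term_similarity
#' @return Similarity in [0, 1], or `NA` if either gene is unannotated
#'   (such pairs are excluded from the GO layer).
#' @export
gene_functional_similarity <- function(g1, g2, annotations, dag,
                                       term_sim = NULL,
                                       contrib = c(is_a = 0.8,
                                                   part_of = 0.6)) {
  t1 <- annotations[[g1]]
  t2 <- annotations[[g2]]
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) {
    return(NA_real_)
  }
  if (is.null(term_sim)) {
    term_sim <- term_similarity_matrix(union(t1, t2), dag, contrib)
  }
  S <- term_sim[t1, t2, drop = FALSE]
  bma(S)
}

bma <- function(S) {
  (mean(apply(S, 1L, max)) + mean(apply(S, 2L, max))) / 2
}

#' Build the GO functional-similarity edge layer
#'
#' Undirected edges connect annotated gene pairs whose best-match-average
#' Wang similarity is strictly above `threshold` (default 0.3); the edge
#' weight is the similarity itself. Unannotated genes get no GO edges but
#' remain valid network nodes.
#'
#' @param genes Character vector of the analysis gene set.
#' @param annotations Named list gene -> term ids.
#' @param dag A `dynafic_ontology`.
#' @param threshold Similarity threshold in [0, 1] (strict `>`).
#' @inheritParams wang_term_similarity
#' @return Edge data.frame (`layer = "go"`, `source < target`).
#' @export
build_go_layer <- function(genes, annotations, dag, threshold = 0.3,
                           contrib = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(threshold >= 0, threshold <= 1)
  genes <- unique(genes)
  annotated <- genes[genes %in% names(annotations)]
  annotated <- annotated[lengths(annotations[annotated]) > 0L]
  src <- character(0); tgt <- character(0); w <- numeric(0)
  if (length(annotated) >= 2L) {
    all_terms <- unique(unlist(annotations[annotated], use.names = FALSE))
    M <- term_similarity_matrix(all_terms, dag, contrib)
    n <- length(annotated)
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- gene_functional_similarity(annotated[i], annotated[j],
                                        annotations, dag, term_sim = M)
        if (!is.na(s) && s > threshold) {
          a <- annotated[i]; b <- annotated[j]
          src <- c(src, min(a, b)); tgt <- c(tgt, max(a, b)); w <- c(w, s)
        }
      }
    }
  }
  edge_frame(src, tgt, "go", w, FALSE)
}
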