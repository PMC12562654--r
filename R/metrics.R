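# Functional-context metrics: cancer-annotation enrichment (CGES),
# ontology depth (GDS) and the composite context modulation index (CMI).

#' Cancer GO enrichment score
#'
#' Fraction of a gene's ontology annotations that belong to a
#' cancer-relevant term list; 0 for unannotated genes. A default list of
#' hallmark-process GO identifiers ships with the package (see
#' [default_cancer_terms()]); its size is configurable and recorded in the
#' run manifest.
#'
#' @param gene Gene symbol.
#' @param annotations Named list gene -> term ids.
#' @param cancer_terms Character vector of cancer-relevant term ids.
#' @return Fraction in [0, 1].
#' @export
cges <- function(gene, annotations, cancer_terms) {
  terms <- annotations[[gene]]
  if (is.null(terms) || !length(terms)) return(0)
  sum(terms %in% cancer_terms) / length(terms)
}

#' GO depth score
#'
#' Mean ontology depth of a gene's annotations, where a term's depth is
#' the length of the longest path up to any root (roots at depth 0).
#' Unannotated genes score 0.
#'
#' @param gene Gene symbol.
#' @param annotations Named list gene -> term ids.
#' @param dag A `dynafic_ontology`.
#' @param rule `"longest"` (default) or `"shortest"` path to a root.
#' @return Nonnegative mean depth.
#' @export
gds <- function(gene, annotations, dag, rule = c("longest", "shortest")) {
  rule <- match.arg(rule)
  terms <- annotations[[gene]]
  if (is.null(terms) || !length(terms)) return(0)
  d <- if (rule == "longest") dag$depth[terms] else shortest_depths(dag)[terms]
  mean(d)
}

# Shortest-path depth variant, memoized per call.
shortest_depths <- function(dag) {
  depth <- stats::setNames(rep(NA_real_, length(dag$terms)), dag$terms)
  get_depth <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    ps <- names(dag$parents[[t]])
    d <- if (!length(ps)) 0 else 1 + min(vapply(ps, get_depth, 0))
    depth[[t]] <<- d
    d
  }
  for (t in dag$terms) get_depth(t)
  depth
}

#' Context modulation index
#'
#' Composite of tissue weight, cancer relevance and ontology depth:
#' `cmi = tanh(theta1 * w * cges) + theta2 * gds / max_gds`. The saturating
#' first term treats `theta1` as a gain on the expression-cancer product;
#' the second adds a bounded depth (specificity) bonus, so the index lies
#' in [0, 1 + theta2] and is monotone in each ingredient.
#'
#' @param w Tissue weight in [0, 1).
#' @param cges_value Cancer enrichment fraction in [0, 1].
#' @param gds_value Mean annotation depth.
#' @param theta1,theta2 Scaling parameters (defaults 2 and 0.1).
#' @param max_gds Maximum depth score over the gene universe (normalizes
#'   the depth bonus); when 0, the depth term is 0.
#' @return Nonnegative index.
#' @export
cmi <- function(w, cges_value, gds_value, theta1 = 2, theta2 = 0.1,
                max_gds = 1) {
  depth_term <- if (max_gds > 0) gds_value / max_gds else 0
  tanh(theta1 * w * cges_value) + theta2 * depth_term
}

#' Per-gene functional profiles for a gene universe
#'
#' Computes CGES, GDS and CMI for each gene; `max_gds` is taken over the
#' supplied universe.
#'
#' @param genes Character vector of gene symbols.
#' @param annotations Named list gene -> term ids.
#' @param dag A `dynafic_ontology`.
#' @param cancer_terms Character vector of cancer-relevant term ids.
#' @param w Named tissue weights (missing genes get 0).
#' @param theta1,theta2 CMI scaling parameters.
#' @return Data.frame with columns `gene`, `w`, `cges`, `gds`, `cmi`.
#' @export
functional_profiles <- function(genes, annotations, dag, cancer_terms,
                                w = NULL, theta1 = 2, theta2 = 0.1) {
  cg <- vapply(genes, cges, 0, annotations = annotations,
               cancer_terms = cancer_terms)
  gd <- vapply(genes, gds, 0, annotations = annotations, dag = dag)
  wg <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(w)) {
    hit <- genes %in% names(w)
    wg[hit] <- w[genes[hit]]
  }
  mg <- max(gd)
  cm <- cmi(wg, cg, gd, theta1 = theta1, theta2 = theta2, max_gds = mg)
  data.frame(gene = genes, w = unname(wg), cges = unname(cg),
             gds = unname(gd), cmi = unname(cm), stringsAsFactors = FALSE)
}

#' Default cancer-relevant GO term list
#'
#' Reads the packaged one-column list of Gene Ontology identifiers for
#' hallmark cancer processes (apoptosis, proliferation, angiogenesis,
#' cell-cycle control, DNA repair, adhesion/migration, canonical oncogenic
#' signalling, immune evasion, metabolic reprogramming). The list is a
#' keyword-derived stand-in for a curated cancer-term catalogue and can be
#' replaced by any one-column file of term ids.
#'
#' @param path Optional path to an alternative one-column term file.
#' @return Character vector of term identifiers.
#' @export
default_cancer_terms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cancer_go_terms.txt",
                        package = "dynafic")
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}
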