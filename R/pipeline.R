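# End-to-end orchestration: one-condition scoring runs and two-condition
# comparison reports.

#' Score one condition from in-memory inputs
#'
#' Runs the full chain: restrict the PPI and TF layers to the analysis
#' gene set (the filtered DE genes), build the GO-similarity layer over
#' that set, integrate the layers, construct the initial influence vector
#' from fold change, significance and tissue weight, diffuse it with
#' regulatory amplification, compute functional profiles, and assemble the
#' score table (including stability-volatility, functional-heterogeneity
#' and trajectory-cluster columns).
#'
#' @param de Filtered DE data.frame from [read_de_table()].
#' @param ppi_edges,tf_edges Edge data.frames (either may be empty/NULL).
#' @param annotations Named list gene -> term ids (may be NULL).
#' @param dag A `dynafic_ontology` (may be NULL when `annotations` is).
#' @param expr Expression data.frame from [read_expression()] (optional).
#' @param cancer_terms Character vector of cancer-relevant term ids;
#'   defaults to the packaged list.
#' @param config A `dynafic_config`.
#' @return Object of class `dynafic_result`: list with `scores`
#'   (the main per-gene table), `network`, `trajectory`, `profiles`,
#'   `clusters`, `config`, and the inputs needed for ablation reruns.
#' @export
dynafic_score <- function(de, ppi_edges = NULL, tf_edges = NULL,
                          annotations = NULL, dag = NULL, expr = NULL,
                          cancer_terms = NULL,
                          config = dynafic_config()) {
  if (!nrow(de)) stop("dynafic_score: empty DE table after filtering")
  genes <- de$gene
  subset_edges <- function(e) {
    if (is.null(e) || !nrow(e)) return(NULL)
    e[e$source %in% genes & e$target %in% genes, , drop = FALSE]
  }
  ppi_sub <- subset_edges(ppi_edges)
  tf_sub <- subset_edges(tf_edges)
  go <- if (!is.null(annotations) && !is.null(dag)) {
    build_go_layer(genes, annotations, dag,
                   threshold = config$go_sim_threshold)
  } else NULL
  network <- integrate_layers(ppi = ppi_sub, tf = tf_sub, go = go,
                              layer_weights = config$layer_weights,
                              nodes = genes)
  w <- if (!is.null(expr)) tissue_weight(expr) else NULL
  x0 <- initial_influence(de, w)
  D <- amplification_operator(network)
  trajectory <- propagate(x0, network, D = D, gamma = config$gamma,
                          T = config$T)
  if (is.null(cancer_terms)) cancer_terms <- default_cancer_terms()
  profiles <- if (!is.null(annotations) && !is.null(dag)) {
    functional_profiles(genes, annotations, dag, cancer_terms, w = w,
                        theta1 = config$theta1, theta2 = config$theta2)
  } else {
    data.frame(gene = genes, w = 0, cges = 0, gds = 0, cmi = 0,
               stringsAsFactors = FALSE)
  }
  scores <- score_table(de, network, trajectory, profiles, config)

  # trajectory-level columns over the scored gene universe
  Xde <- trajectory$X[genes, , drop = FALSE]
  cent <- stats::setNames(scores$centrality, scores$gene)
  svi_v <- svi(Xde, cent)
  cats <- derive_categories(genes, annotations, dag)
  fh_v <- functional_heterogeneity(network, cats)
  clusters <- if (length(genes) >= 4L) {
    cluster_trajectories(Xde, seed = config$seed)
  } else NULL
  scores$svi <- unname(svi_v[scores$gene])
  scores$fh <- unname(fh_v[scores$gene])
  scores$cluster <- if (!is.null(clusters)) {
    unname(clusters$labels[scores$gene])
  } else NA_character_
  structure(list(scores = scores, network = network,
                 trajectory = trajectory, profiles = profiles,
                 clusters = clusters, config = config, de = de,
                 annotations = annotations, dag = dag, expr = expr,
                 cancer_terms = cancer_terms),
            class = "dynafic_result")
}

#' @export
print.dynafic_result <- function(x, ...) {
  cat(sprintf("DynaFIC run: %d genes scored; top gene %s (scaled %.2f)\n",
              nrow(x$scores), x$scores$gene[1L],
              x$scores$dynafic_scaled[1L]))
  invisible(x)
}

# Functional category of a gene: the depth-1 ontology branch holding most
# of its annotations (ties broken lexicographically); "Other" when
# unannotated or rooted only.
derive_categories <- function(genes, annotations, dag) {
  out <- stats::setNames(rep("Other", length(genes)), genes)
  if (is.null(annotations) || is.null(dag)) return(out)
  branch_of <- function(term) {
    anc <- term_ancestors(term, dag)
    b <- anc[dag$depth[anc] == 1]
    if (!length(b)) character(0) else b
  }
  for (g in genes) {
    terms <- annotations[[g]]
    if (is.null(terms) || !length(terms)) next
    branches <- unlist(lapply(terms, branch_of), use.names = FALSE)
    if (!length(branches)) next
    tab <- sort(table(branches), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    out[[g]] <- sort(top)[1L]
  }
  out
}

#' Score one condition from input files
#'
#' File-level wrapper over [dynafic_score()]: reads every input, runs the
#' pipeline, and writes `scores.tsv`, `trajectory.tsv`, the integrated
#' edge list `network_edges.tsv`, and `manifest.json` into `out_dir`.
#' A missing TF file runs with an empty regulatory layer (with a
#' warning); annotations/ontology/expression are likewise optional.
#'
#' @param de,ppi,tf,obo,annotations,expression Input file paths (all but
#'   `de` may be `NULL`).
#' @param cancer_terms Optional path to a one-column cancer-term list.
#' @param config A `dynafic_config` (or path to a YAML config).
#' @param out_dir Output directory.
#' @return The `dynafic_result`, invisibly.
#' @export
run_score <- function(de, ppi = NULL, tf = NULL, obo = NULL,
                      annotations = NULL, expression = NULL,
                      cancer_terms = NULL, config = dynafic_config(),
                      out_dir = ".") {
  if (is.character(config)) config <- read_config(config)
  t0 <- proc.time()[["elapsed"]]
  de_tab <- read_de_table(de, padj_max = config$de_padj_max,
                          abs_lfc_min = config$de_abs_lfc_min)
  ppi_e <- if (!is.null(ppi)) {
    read_ppi_edges(ppi, min_score = config$ppi_min_score)
  } else NULL
  tf_e <- if (!is.null(tf)) {
    read_tf_edges(tf)
  } else {
    warning("run_score: no TF file supplied; regulatory layer is empty")
    NULL
  }
  dag <- if (!is.null(obo)) read_ontology(obo) else NULL
  ann <- if (!is.null(annotations) && !is.null(dag)) {
    read_annotations(annotations, dag)
  } else NULL
  expr <- if (!is.null(expression)) read_expression(expression) else NULL
  ct <- if (!is.null(cancer_terms)) {
    default_cancer_terms(cancer_terms)
  } else NULL
  t_read <- proc.time()[["elapsed"]]
  result <- dynafic_score(de_tab, ppi_e, tf_e, ann, dag, expr, ct,
                          config = config)
  t_run <- proc.time()[["elapsed"]]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_trajectory(result$trajectory,
                   file.path(out_dir, "trajectory.tsv"))
  all_edges <- do.call(rbind, result$network$layers)
  write_edges(all_edges, file.path(out_dir, "network_edges.tsv"))
  inputs <- c(de = de, ppi = ppi, tf = tf, obo = obo,
              annotations = annotations, expression = expression,
              cancer_terms = cancer_terms)
  write_manifest(file.path(out_dir, "manifest.json"), config,
                 inputs = unlist(inputs),
                 timings = c(read = t_read - t0, score = t_run - t_read),
                 extra = list(n_genes_scored = nrow(result$scores),
                              n_cancer_terms = length(
                                if (is.null(ct)) default_cancer_terms() else ct)))
  invisible(result)
}

# PPI-only rerun of a completed result (multi-scale ablation).
ablation_score <- function(result) {
  cfg <- result$config
  dynafic_score(result$de,
                ppi_edges = result$network$layers$ppi,
                tf_edges = NULL, annotations = NULL, dag = NULL,
                expr = result$expr,
                cancer_terms = result$cancer_terms, config = cfg)
}

#' Compare two scored conditions
#'
#' Produces the two-condition comparison report: the 1-D Wasserstein
#' distance between the scaled score distributions with a label-permutation
#' p-value, Welch's t-test on the stability-volatility indices, the
#' per-condition Pearson correlation between |log2FC| and scaled score,
#' functional-hierarchy disruption (distributional Wasserstein plus
#' 2-standard-deviation gene outliers over shared genes), per-condition
#' trajectory cluster reports, hypergeometric enrichment of
#' tissue-expressed genes among high-modulation (top-quartile CMI) genes,
#' and the Spearman agreement of each condition's full versus PPI-only
#' rankings.
#'
#' @param left,right `dynafic_result` objects.
#' @param reference `"left"`, `"right"` or `NULL`: when set, scaled
#'   scores of both conditions are re-expressed on the reference
#'   condition's 0-100 scale before the distributional comparison.
#' @param permutations Label permutations for the Wasserstein null.
#' @param seed Seed for the permutation draw.
#' @return Object of class `dynafic_comparison` (a named list; see
#'   Details in the vignette).
#' @export
dynafic_compare <- function(left, right, reference = NULL,
                            permutations = NULL, seed = NULL) {
  cfg <- left$config
  if (is.null(permutations)) permutations <- cfg$permutations
  if (is.null(seed)) seed <- cfg$seed
  raw <- list(left = stats::setNames(left$scores$dynafic_raw,
                                     left$scores$gene),
              right = stats::setNames(right$scores$dynafic_raw,
                                      right$scores$gene))
  scaled <- scale_scores(raw, reference = reference)
  wt <- wasserstein_permutation_p(scaled$left, scaled$right,
                                  B = permutations, seed = seed)
  svi_l <- left$scores$svi
  svi_r <- right$scores$svi
  welch <- welch_t(svi_l, svi_r)
  r_l <- expression_influence_correlation(left$de, left$scores)
  r_r <- expression_influence_correlation(right$de, right$scores)
  fh_l <- stats::setNames(left$scores$fh, left$scores$gene)
  fh_r <- stats::setNames(right$scores$fh, right$scores$gene)
  disruption <- hierarchy_disruption(fh_l, fh_r)
  enr <- vapply(list(left, right), function(res) {
    universe <- res$scores$gene
    tissue_pos <- universe[res$profiles$w[match(universe,
                                                res$profiles$gene)] > 0]
    q <- stats::quantile(res$scores$cmi, 0.75)
    high_cmi <- universe[res$scores$cmi >= q]
    hypergeom_enrichment(high_cmi, tissue_pos, universe)
  }, 0)
  abl <- vapply(list(left, right), function(res) {
    ablation_compare(res$scores, ablation_score(res)$scores)
  }, 0)
  structure(list(
    wasserstein = wt$statistic,
    wasserstein_p = wt$p,
    welch_t = welch$t, welch_p = welch$p,
    pearson_r = c(left = r_l, right = r_r),
    svi_mean = c(left = mean(svi_l), right = mean(svi_r)),
    fh_wasserstein = disruption$wasserstein,
    disrupted_genes = disruption$disrupted,
    n_shared = disruption$n_shared,
    partial_shared = disruption$n_shared < 3L,
    enrichment_p = c(left = enr[1L], right = enr[2L]),
    ablation_spearman = c(left = abl[1L], right = abl[2L]),
    clusters = list(left = left$clusters, right = right$clusters),
    reference = if (is.null(reference)) "per-condition" else reference
  ), class = "dynafic_comparison")
}

#' @export
print.dynafic_comparison <- function(x, ...) {
  cat("Two-condition comparison\n")
  cat(sprintf("  score Wasserstein = %.4f (permutation p = %.4g)\n",
              x$wasserstein, x$wasserstein_p))
  cat(sprintf("  SVI Welch t = %.3f (p = %.3g); means %.3f vs %.3f\n",
              x$welch_t, x$welch_p, x$svi_mean[["left"]],
              x$svi_mean[["right"]]))
  cat(sprintf("  expression-influence r: left %.3f, right %.3f\n",
              x$pearson_r[["left"]], x$pearson_r[["right"]]))
  cat(sprintf("  FH Wasserstein = %.4g; %d disrupted gene(s) of %d shared\n",
              x$fh_wasserstein, length(x$disrupted_genes), x$n_shared))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param comparison A `dynafic_comparison`.
#' @param path Output JSON path.
#' @export
write_comparison <- function(comparison, path) {
  out <- unclass(comparison)
  out$clusters <- lapply(out$clusters, function(cl) {
    if (is.null(cl)) return(NULL)
    list(k = cl$k, silhouette = cl$silhouette,
         labels = as.list(cl$labels), degenerate = cl$degenerate)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
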