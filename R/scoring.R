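# Composite scoring: final-step influence x context modulation x omega1
# plus omega2 x normalized degree centrality, then log1p scaling to a
# 0-100 reference range and deterministic ranking.

#' Raw composite influence score
#'
#' `score = x_T * cmi * omega1 + omega2 * centrality`. Linear in the
#' centrality component, so genes with zero context modulation retain a
#' pure centrality floor.
#'
#' @param x_T Final-step diffused influence (nonnegative).
#' @param cmi Context modulation index.
#' @param centrality Normalized degree centrality in [0, 1].
#' @param omega1,omega2 Nonnegative component weights (defaults 0.8, 0.4).
#' @return Nonnegative score (vectorized).
#' @export
dynafic_raw <- function(x_T, cmi, centrality, omega1 = 0.8, omega2 = 0.4) {
  stopifnot(all(x_T >= 0), all(centrality >= 0), omega1 >= 0, omega2 >= 0)
  x_T * cmi * omega1 + omega2 * centrality
}

#' Log-transform and scale raw scores to a 0-100 range
#'
#' Scores are transformed with `log1p` (natural log; handles zero raw
#' scores) and rescaled so the top gene reaches 100. In per-condition mode
#' (default) each condition is scaled by its own maximum. In reference
#' mode every condition is scaled by the reference condition's maximum, so
#' genes elsewhere may exceed 100 — the only mode in which one condition's
#' top score can be, e.g., exactly twice the other's.
#'
#' @param raw Named list of conditions, each a named numeric vector of
#'   raw scores (all >= 0).
#' @param reference Condition name to scale against, or `NULL` for
#'   per-condition scaling.
#' @return Named list of scaled score vectors (same shape as `raw`).
#' @export
scale_scores <- function(raw, reference = NULL) {
  stopifnot(is.list(raw), length(raw) >= 1L)
  s <- lapply(raw, function(v) {
    if (any(v < 0)) stop("scale_scores: negative raw score")
    log1p(v)
  })
  if (!is.null(reference)) {
    if (!reference %in% names(raw)) {
      stop("scale_scores: unknown reference condition '", reference, "'")
    }
    denom <- max(s[[reference]])
    if (denom == 0) stop("scale_scores: all reference scores are zero")
    lapply(s, function(v) 100 * v / denom)
  } else {
    lapply(s, function(v) {
      if (max(v) == 0) stop("scale_scores: all scores are zero")
      100 * v / max(v)
    })
  }
}

#' Packaged top-20 laterality score table
#'
#' The published top-20 composite scores per anatomical side (gene, scaled
#' score, log2 fold change, adjusted p), shipped as a plain-TSV worked
#' example for the scaling and amplification-ratio utilities.
#'
#' @return Data.frame with columns `side`, `rank`, `gene`, `score`,
#'   `log2fc`, `padj`.
#' @export
laterality_top20 <- function() {
  path <- system.file("extdata", "crc_laterality_top20.tsv",
                      package = "dynafic")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Assemble the per-gene score table for one condition
#'
#' Joins differential expression, final-step influence, centrality and the
#' functional profile into one row per DE gene, computes raw and scaled
#' scores, and ranks genes by scaled score with ties broken by smaller
#' adjusted p, then lexicographic gene symbol.
#'
#' @param de Filtered DE data.frame (`gene`, `log2fc`, `pvalue`, `padj`).
#' @param network A `dynafic_network` containing every DE gene.
#' @param trajectory A `dynafic_trajectory` over the network nodes.
#' @param profiles Data.frame from [functional_profiles()].
#' @param config A `dynafic_config`.
#' @return Data.frame with one row per DE gene, sorted by rank, columns
#'   `gene`, `log2fc`, `padj`, `x_T`, `centrality`, `cges`, `gds`, `cmi`,
#'   `dynafic_raw`, `dynafic_scaled`, `rank`.
#' @export
score_table <- function(de, network, trajectory, profiles, config) {
  genes <- de$gene
  missing <- setdiff(genes, trajectory$genes)
  if (length(missing)) {
    stop("score_table: genes missing from trajectory: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  missing <- setdiff(genes, profiles$gene)
  if (length(missing)) {
    stop("score_table: genes missing from profiles: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x_T <- trajectory$X[genes, ncol(trajectory$X)]
  cent <- stats::setNames(rep(0, length(genes)), genes)
  if (length(network$nodes) >= 2L) {
    all_cent <- degree_centrality(network)
    hit <- genes %in% names(all_cent)
    cent[hit] <- all_cent[genes[hit]]
  }
  prof <- profiles[match(genes, profiles$gene), , drop = FALSE]
  raw <- dynafic_raw(x_T, prof$cmi, cent,
                     omega1 = config$omega1, omega2 = config$omega2)
  scaled <- scale_scores(list(run = raw))$run
  ord <- order(-scaled, de$padj, genes)
  out <- data.frame(
    gene = genes, log2fc = de$log2fc, padj = de$padj,
    x_T = unname(x_T), centrality = unname(cent),
    cges = prof$cges, gds = prof$gds, cmi = prof$cmi,
    dynafic_raw = unname(raw), dynafic_scaled = unname(scaled),
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
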