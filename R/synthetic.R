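# Synthetic fixture generators: STRING-, TRRUST-, OBO-, GTEx- and
# DE-table-style files with controllable statistical structure, so the
# full pipeline runs with no external downloads.

#' Specification of a synthetic scenario
#'
#' Describes one condition's input bundle: network model and density,
#' regulator count and out-degree law, ontology shape, the fraction of DE
#' genes passing the default significance thresholds, the effect-size and
#' adjusted-p laws, the tissue-expression law, and an optional planted hub
#' forced to the top combined degree and top TF out-degree.
#'
#' Significant genes draw |log2FC| from a lognormal law truncated below at
#' `abs_lfc_min` (heavy-tailed fold changes of roughly 0.6-4) and adjusted
#' p-values as `10^-U(1.3, 20)` with the exponent floored just above
#' `-log10(0.05)` so the planted significance count is exact. With
#' `padj_couple = TRUE` the exponent instead grows linearly with |log2FC|
#' plus noise, emulating a hierarchical condition where large effects are
#' also the most significant.
#'
#' @param n_genes Number of genes.
#' @param ppi_model `"erdos_renyi"` (`ppi_param` = edge probability),
#'   `"scale_free"` (`ppi_param` = edges added per vertex), or
#'   `"hierarchical"` (`ppi_param` = edge probability; attachment odds
#'   proportional to |log2FC|, so expression magnitude determines network
#'   position — the signature of a hierarchical, expression-driven
#'   architecture).
#' @param ppi_param Density parameter of the PPI model.
#' @param n_tfs Number of transcription factors.
#' @param tf_outdeg_lambda Poisson rate of TF out-degrees (out-degree is
#'   `1 + Poisson(lambda)`).
#' @param onto_depth,onto_branching Depth and per-level branching factors
#'   (recycled over levels) of the generated ontology tree, plus sparse
#'   random deeper-to-shallower cross links (`is_a` only). The default
#'   7-level shape separates functional modules (depth-4 subtrees) cleanly
#'   under the Wang measure: within-module leaf pairs score ~0.4,
#'   sibling-module pairs ~0.28.
#' @param ann_within_prob Probability that an annotation term is drawn
#'   from the gene's own functional module rather than anywhere: high
#'   values give functionally compartmentalized genes, low values give
#'   cross-functionally integrated ones.
#' @param frac_significant Fraction of genes passing the default DE
#'   thresholds (exact count `round(frac * n_genes)` by construction).
#' @param lfc_meanlog,lfc_sdlog Lognormal parameters of |log2FC|.
#' @param padj_couple Couple the significance exponent to |log2FC|.
#' @param expr_meanlog,expr_sdlog Lognormal parameters of tissue
#'   expression.
#' @param planted_hub `NULL`, `TRUE` (first gene) or a gene name: forces
#'   that gene to the strictly maximal combined degree and TF out-degree.
#' @param hub_frac Fraction of genes the planted hub connects to.
#' @param hub_lfc Optional fixed |log2FC| for the planted hub (a hub with
#'   modest expression change but dominant topology).
#' @param cancer_frac Fraction of ontology terms marked cancer-relevant.
#' @param de_padj_max,de_abs_lfc_min The thresholds the significance
#'   fraction refers to.
#' @param gene_prefix Prefix of generated gene symbols (conditions that
#'   must not share genes use different prefixes).
#' @param seed Integer seed; generation is byte-deterministic given it.
#' @return Object of class `dynafic_scenario` (a named list).
#' @export
scenario_spec <- function(n_genes = 100L,
                          ppi_model = c("erdos_renyi", "scale_free",
                                        "hierarchical"),
                          ppi_param = 0.08,
                          n_tfs = 5L,
                          tf_outdeg_lambda = 3,
                          onto_depth = 7L,
                          onto_branching = c(3L, 3L, 3L, 3L, 2L, 2L, 2L),
                          ann_within_prob = 0.75,
                          frac_significant = 0.4,
                          lfc_meanlog = log(1.1),
                          lfc_sdlog = 0.6,
                          padj_couple = FALSE,
                          expr_meanlog = 3,
                          expr_sdlog = 1,
                          planted_hub = NULL,
                          hub_frac = 0.5,
                          hub_lfc = NULL,
                          cancer_frac = 0.2,
                          de_padj_max = 0.05,
                          de_abs_lfc_min = 0.58,
                          gene_prefix = "g",
                          seed = 1L) {
  ppi_model <- match.arg(ppi_model)
  stopifnot(frac_significant >= 0, frac_significant <= 1, n_genes >= 5L,
            n_tfs >= 1L, n_tfs < n_genes)
  spec <- as.list(environment())
  class(spec) <- "dynafic_scenario"
  spec
}

scenario_genes <- function(spec) {
  sprintf("%s%03d", spec$gene_prefix, seq_len(spec$n_genes))
}

# Tree ontology with `onto_branching` children per node down to
# `onto_depth`, plus sparse deeper-to-shallower cross links (acyclic by
# construction).
generate_ontology <- function(spec) {
  branching <- rep_len(spec$onto_branching, spec$onto_depth)
  levels <- list("T0001")
  counter <- 1L
  parents <- list(T0001 = character(0))
  for (d in seq_len(spec$onto_depth)) {
    prev <- levels[[d]]
    cur <- character(0)
    for (p in prev) {
      for (b in seq_len(branching[d])) {
        counter <- counter + 1L
        id <- sprintf("T%04d", counter)
        parents[[id]] <- stats::setNames("is_a", p)
        cur <- c(cur, id)
      }
    }
    levels[[d + 1L]] <- cur
  }
  terms <- unlist(levels, use.names = FALSE)
  tree_parent <- vapply(terms, function(t) {
    p <- names(parents[[t]])
    if (length(p)) p[1L] else NA_character_
  }, "")
  n_cross <- max(1L, round(0.005 * length(terms)))
  depth_of <- rep(seq_along(levels) - 1L, lengths(levels))
  names(depth_of) <- terms
  deep <- terms[depth_of >= 2L]
  for (i in seq_len(n_cross)) {
    child <- sample(deep, 1L)
    shallow <- terms[depth_of < depth_of[[child]]]
    extra <- sample(shallow, 1L)
    if (!extra %in% names(parents[[child]])) {
      parents[[child]] <- c(parents[[child]],
                            stats::setNames("is_a", extra))
    }
  }
  dag <- ontology_from_parents(parents)
  dag$tree_parent <- tree_parent
  dag
}

# Tree ancestor of `term` at `depth`, following primary (tree) parents.
tree_ancestor_at <- function(term, dag, depth) {
  t <- term
  while (!is.na(t) && dag$depth[[t]] > depth) t <- dag$tree_parent[[t]]
  if (is.na(t) || dag$depth[[t]] != depth) NA_character_ else t
}

write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    rels <- dag$parents[[t]]
    for (i in seq_along(rels)) {
      p <- names(rels)[i]
      if (rels[[i]] == "is_a") {
        writeLines(paste0("is_a: ", p), con)
      } else {
        writeLines(paste0("relationship: part_of ", p), con)
      }
    }
  }
  invisible(path)
}

#' Generate a synthetic input bundle
#'
#' Writes a full set of pipeline inputs to `dir`: `ppi.tsv` (STRING-style
#' with a bimodal combined-score distribution), `tf.tsv` (TRRUST-style,
#' header included), `ontology.obo`, `annotations.tsv`, `expression.tsv`,
#' `cancer_terms.txt`, and `de.csv`. Generation is deterministic given
#' `spec$seed`; the planted hub (if any) gets the strictly maximal
#' combined degree and TF out-degree, and exactly
#' `round(frac_significant * n_genes)` DE rows pass the default
#' thresholds.
#'
#' @param spec A `dynafic_scenario` from [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `genes`,
#'   `significant` (planted significant genes) and `hub`.
#' @export
generate_scenario <- function(spec, dir) {
  stopifnot(inherits(spec, "dynafic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  genes <- scenario_genes(spec)
  n <- spec$n_genes
  hub <- NULL
  if (!is.null(spec$planted_hub) && !isFALSE(spec$planted_hub)) {
    hub <- if (isTRUE(spec$planted_hub)) genes[1L] else spec$planted_hub
    if (!hub %in% genes) stop("planted hub is not one of the genes")
    if (ceiling(spec$hub_frac * (n - 1L)) > n - 1L) {
      stop("infeasible spec: hub degree would exceed n - 1")
    }
  }

  ## --- DE statistics (drawn first: the hierarchical network model
  ## couples degree to effect size, so fold changes must exist already) --
  n_sig <- round(spec$frac_significant * n)
  sig <- if (!is.null(hub) && n_sig >= 1L) {
    c(hub, sample(setdiff(genes, hub), n_sig - 1L))
  } else {
    sample(genes, n_sig)
  }
  is_sig <- genes %in% sig
  lfc_abs <- numeric(n)
  # truncated lognormal above the fold-change threshold for significant genes
  draw_trunc <- function(k) {
    out <- numeric(0)
    while (length(out) < k) {
      draw <- stats::rlnorm(k, spec$lfc_meanlog, spec$lfc_sdlog)
      out <- c(out, draw[draw > spec$de_abs_lfc_min])
    }
    out[seq_len(k)]
  }
  lfc_abs[is_sig] <- draw_trunc(sum(is_sig))
  lfc_abs[!is_sig] <- stats::rlnorm(sum(!is_sig), spec$lfc_meanlog,
                                    spec$lfc_sdlog)
  if (!is.null(hub) && !is.null(spec$hub_lfc) && hub %in% sig) {
    lfc_abs[genes == hub] <- spec$hub_lfc
  }
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- sgn * lfc_abs
  padj <- numeric(n)
  exp_floor <- -log10(spec$de_padj_max) + 1e-3
  if (spec$padj_couple) {
    u <- 1.5 + 6 * (lfc_abs[is_sig] - spec$de_abs_lfc_min) +
      stats::rnorm(sum(is_sig), 0, 0.8)
  } else {
    u <- stats::runif(sum(is_sig), 1.3, 20)
  }
  u <- pmin(pmax(u, exp_floor), 20)
  padj[is_sig] <- 10^(-u)
  padj[!is_sig] <- stats::runif(sum(!is_sig), spec$de_padj_max + 0.01, 0.9)
  pval <- padj * stats::runif(n, 0.05, 1)

  ## --- PPI layer -------------------------------------------------------
  if (spec$ppi_model == "hierarchical") {
    # expression-driven compartmentalized architecture: attachment odds
    # proportional to effect size (large-|log2FC| genes occupy central
    # positions) and restricted to nearby expression strata, so each
    # compartment links genes of comparable influence
    m_target <- round(spec$ppi_param * n * (n - 1L) / 2)
    s <- lfc_abs + 0.05
    rk <- rank(-lfc_abs, ties.method = "first")
    window <- max(6L, round(n / 10))
    a <- character(0); b <- character(0)
    for (round_i in 1:200) {
      if (length(a) >= m_target) break
      need <- m_target - length(a)
      i <- sample.int(n, 4L * need + 10L, replace = TRUE, prob = s)
      j <- sample.int(n, 4L * need + 10L, replace = TRUE, prob = s)
      keep <- i != j & abs(rk[i] - rk[j]) <= window
      a <- c(a, pmin(genes[i[keep]], genes[j[keep]]))
      b <- c(b, pmax(genes[i[keep]], genes[j[keep]]))
      dup <- duplicated(paste(a, b, sep = "\r"))
      a <- a[!dup]; b <- b[!dup]
      if (length(a) > m_target) {
        a <- a[seq_len(m_target)]; b <- b[seq_len(m_target)]
      }
    }
  } else {
    g <- if (spec$ppi_model == "erdos_renyi") {
      igraph::sample_gnp(n, spec$ppi_param)
    } else {
      igraph::sample_pa(n, m = max(1L, round(spec$ppi_param)),
                        directed = FALSE)
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    a <- genes[el[, 1L]]
    b <- genes[el[, 2L]]
  }
  if (!is.null(hub)) {
    keep <- a != hub & b != hub
    a <- a[keep]; b <- b[keep]
    deg <- table(factor(c(a, b), levels = genes))
    k <- max(ceiling(spec$hub_frac * (n - 1L)),
             as.integer(max(deg)) + 2L)
    if (k > n - 1L) stop("infeasible spec: hub degree would exceed n - 1")
    nb <- sample(setdiff(genes, hub), k)
    a <- c(a, rep(hub, k)); b <- c(b, nb)
  }
  m <- length(a)
  comp <- sample(1:2, m, replace = TRUE)
  score <- round(pmin(999, pmax(150,
                                stats::rnorm(m, c(500, 850)[comp],
                                             c(80, 60)[comp]))))
  if (!is.null(hub)) {
    score[a == hub | b == hub] <-
      round(stats::runif(sum(a == hub | b == hub), 850, 999))
  }
  ppi_path <- file.path(dir, "ppi.tsv")
  utils::write.table(data.frame(protein1 = a, protein2 = b,
                                combined_score = as.integer(score)),
                     ppi_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- TF layer --------------------------------------------------------
  others <- setdiff(genes, hub)
  tfs <- sample(others, spec$n_tfs)
  tf_src <- character(0); tf_tgt <- character(0)
  for (tf in tfs) {
    k <- 1L + stats::rpois(1L, spec$tf_outdeg_lambda)
    k <- min(k, n - 1L)
    tf_tgt <- c(tf_tgt, sample(setdiff(genes, tf), k))
    tf_src <- c(tf_src, rep(tf, k))
  }
  if (!is.null(hub)) {
    base_max <- max(table(tf_src))
    k <- min(base_max + 3L, n - 1L)
    tf_src <- c(tf_src, rep(hub, k))
    tf_tgt <- c(tf_tgt, sample(setdiff(genes, hub), k))
  }
  tf_df <- unique(data.frame(TF = tf_src, target = tf_tgt,
                             stringsAsFactors = FALSE))
  tf_path <- file.path(dir, "tf.tsv")
  utils::write.table(tf_df, tf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- Ontology, annotations, cancer terms -----------------------------
  dag <- generate_ontology(spec)
  obo_path <- file.path(dir, "ontology.obo")
  write_obo(dag, obo_path)
  # Annotations are module-structured, as real GO annotation of a DE gene
  # set is: each gene belongs to one functional module (a depth-2 subtree)
  # and draws specific (deep) terms mostly from it. This yields the
  # right-skewed gene-pair similarity profile of real data: within-module
  # pairs clear the 0.3 threshold, cross-module pairs rarely do.
  depths <- dag$depth
  cand <- dag$terms[depths >= spec$onto_depth - 1L]
  wcand <- ifelse(depths[cand] == spec$onto_depth, 1, 0.15)
  mod_depth <- max(1L, spec$onto_depth - 3L)
  mods <- dag$terms[depths == mod_depth]
  mod_of <- vapply(cand, tree_ancestor_at, "", dag = dag,
                   depth = mod_depth)
  ann_gene <- character(0); ann_term <- character(0)
  for (gn in genes) {
    mod <- sample(mods, 1L)
    inmod <- cand[!is.na(mod_of) & mod_of == mod]
    k <- sample(2:4, 1L)
    ts <- vapply(seq_len(k), function(j) {
      if (stats::runif(1L) < spec$ann_within_prob && length(inmod)) {
        sample(inmod, 1L, prob = wcand[match(inmod, cand)])
      } else {
        sample(cand, 1L, prob = wcand)
      }
    }, "")
    ann_gene <- c(ann_gene, rep(gn, k))
    ann_term <- c(ann_term, ts)
  }
  ann_df <- unique(data.frame(gene = ann_gene, term = ann_term,
                              stringsAsFactors = FALSE))
  ann_path <- file.path(dir, "annotations.tsv")
  utils::write.table(ann_df, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cancer <- sort(sample(dag$terms,
                        max(1L, ceiling(spec$cancer_frac *
                                          length(dag$terms)))))
  cancer_path <- file.path(dir, "cancer_terms.txt")
  writeLines(cancer, cancer_path)

  ## --- Tissue expression -----------------------------------------------
  expr <- stats::rlnorm(n, spec$expr_meanlog, spec$expr_sdlog)
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = genes,
                                expr = round(expr, 4L)),
                     expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- DE table --------------------------------------------------------
  de_path <- file.path(dir, "de.csv")
  utils::write.table(data.frame(gene = genes,
                                log2fc = signif(lfc, 6L),
                                pvalue = signif(pval, 6L),
                                padj = signif(padj, 6L)),
                     de_path, sep = ",", quote = FALSE, row.names = FALSE)

  invisible(list(
    paths = c(ppi = ppi_path, tf = tf_path, obo = obo_path,
              annotations = ann_path, expression = expr_path,
              cancer_terms = cancer_path, de = de_path),
    genes = genes, significant = sort(sig), hub = hub, tfs = tfs
  ))
}

#' Generate a paired two-condition scenario
#'
#' Emulates the contrast between a hierarchical condition (sparse network,
#' wide effect-size range, significance coupled to effect size, no hub)
#' and a hub-amplified condition (dense network, compressed effect sizes,
#' independent significance, planted hub with a modest fold change).
#' Default sizes mirror a 59-gene sparse versus 46-gene dense design.
#'
#' @param dir Output directory; bundles land in `dir/left` and
#'   `dir/right`.
#' @param spec_left,spec_right Optional scenario overrides; defaults
#'   encode the hierarchical (left) and hub-amplified (right) conditions.
#' @param shared_gene_frac Fraction of the right condition's genes reusing
#'   left-condition symbols (shared-gene analytics need an overlap).
#' @param seed Master seed; condition seeds derive from it.
#' @return List with `left` and `right` bundle descriptors (as returned
#'   by [generate_scenario()]).
#' @export
two_condition_scenario <- function(dir, spec_left = NULL,
                                   spec_right = NULL,
                                   shared_gene_frac = 0.2,
                                   seed = 1L) {
  stopifnot(shared_gene_frac >= 0, shared_gene_frac <= 1)
  if (is.null(spec_left)) {
    spec_left <- scenario_spec(
      n_genes = 120L, ppi_model = "hierarchical", ppi_param = 0.04,
      n_tfs = 6L, frac_significant = 59 / 120,
      lfc_meanlog = log(1.1), lfc_sdlog = 0.7, padj_couple = TRUE,
      ann_within_prob = 0.9, seed = seed)
  }
  if (is.null(spec_right)) {
    spec_right <- scenario_spec(
      n_genes = 80L, ppi_model = "erdos_renyi", ppi_param = 0.30,
      n_tfs = 12L, tf_outdeg_lambda = 8, frac_significant = 46 / 80,
      lfc_meanlog = log(0.9), lfc_sdlog = 0.35, padj_couple = FALSE,
      planted_hub = TRUE, hub_frac = 0.6, hub_lfc = 1.59,
      ann_within_prob = 0.45, gene_prefix = "r", seed = seed + 1L)
  }
  left <- generate_scenario(spec_left, file.path(dir, "left"))
  right <- generate_scenario(spec_right, file.path(dir, "right"))
  if (shared_gene_frac > 0) {
    # rename a fraction of right genes to left symbols across all files
    set.seed(seed + 2L)
    n_shared <- floor(shared_gene_frac * spec_right$n_genes)
    from <- sample(right$genes, n_shared)
    to <- sample(left$genes, n_shared)
    map <- stats::setNames(to, from)
    rename_in <- function(path, sep) {
      df <- utils::read.table(path, header = TRUE, sep = sep,
                              colClasses = "character",
                              check.names = FALSE)
      for (cl in 1:2) {
        hit <- df[[cl]] %in% names(map)
        df[[cl]][hit] <- map[df[[cl]][hit]]
      }
      utils::write.table(df, path, sep = sep, quote = FALSE,
                         row.names = FALSE)
    }
    rename_one <- function(path, sep) {
      df <- utils::read.table(path, header = TRUE, sep = sep,
                              colClasses = "character",
                              check.names = FALSE)
      hit <- df[[1L]] %in% names(map)
      df[[1L]][hit] <- map[df[[1L]][hit]]
      utils::write.table(df, path, sep = sep, quote = FALSE,
                         row.names = FALSE)
    }
    rename_in(right$paths[["ppi"]], "\t")
    rename_in(right$paths[["tf"]], "\t")
    rename_one(right$paths[["annotations"]], "\t")
    rename_one(right$paths[["expression"]], "\t")
    rename_one(right$paths[["de"]], ",")
    right$genes[match(from, right$genes)] <- to
    right$significant[right$significant %in% from] <-
      map[right$significant[right$significant %in% from]]
    if (!is.null(right$hub) && right$hub %in% from) {
      right$hub <- map[[right$hub]]
    }
  }
  list(left = left, right = right,
       spec_left = spec_left, spec_right = spec_right)
}
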