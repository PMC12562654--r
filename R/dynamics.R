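# Trajectory-level and two-condition analytics: volatility and
# heterogeneity indices, hierarchy disruption, Wasserstein machinery,
# clustering, correlation and enrichment statistics.

#' Stability volatility index
#'
#' Combines trajectory variability with network centrality: each gene's
#' coefficient of variation over time is normalized by the maximum CV in
#' the universe, then multiplied by the affine centrality factor
#' `0.5 + 0.5 * centrality`. Flat trajectories therefore score 0
#' regardless of centrality, and only the most volatile, most central gene
#' can reach 1.
#'
#' @param trajectory A `dynafic_trajectory` (or a genes x time matrix).
#' @param centrality Named centrality vector; genes absent get 0.
#' @return Named numeric vector of SVI values in [0, 1].
#' @export
svi <- function(trajectory, centrality) {
  X <- if (inherits(trajectory, "dynafic_trajectory")) trajectory$X else trajectory
  stopifnot(ncol(X) >= 2L)
  cv <- apply(X, 1L, function(row) stats::sd(row) / (mean(row) + 1e-12))
  mx <- max(cv)
  cvhat <- if (mx > 0) cv / mx else cv * 0
  cent <- stats::setNames(rep(0, nrow(X)), rownames(X))
  hit <- rownames(X) %in% names(centrality)
  cent[hit] <- centrality[rownames(X)[hit]]
  stats::setNames(cvhat * (0.5 + 0.5 * cent), rownames(X))
}

#' Functional heterogeneity of network neighborhoods
#'
#' For each gene, the Shannon entropy (natural log) of functional-category
#' frequencies over its closed 1-hop neighborhood in the combined
#' undirected network, normalized by `log` of the number of categories
#' present in the whole universe, and scaled by the neighborhood fraction
#' `degree / |V|`. Isolated genes score 0.
#'
#' @param network A `dynafic_network`.
#' @param category_map Named character vector gene -> functional category;
#'   genes without an entry fall in `"Other"`.
#' @return Named numeric vector of FH scores in [0, 1].
#' @export
functional_heterogeneity <- function(network, category_map = NULL) {
  nodes <- network$nodes
  nV <- length(nodes)
  cats <- stats::setNames(rep("Other", nV), nodes)
  if (!is.null(category_map)) {
    hit <- nodes %in% names(category_map)
    cats[hit] <- category_map[nodes[hit]]
  }
  k_universe <- length(unique(cats))
  U <- network$A + Matrix::t(network$A)
  Matrix::diag(U) <- 0
  adj <- U > 0
  fh <- vapply(seq_len(nV), function(i) {
    nb <- which(adj[i, ])
    if (!length(nb)) return(0)
    cc <- cats[c(i, nb)]
    p <- table(cc) / length(cc)
    H <- -sum(p * log(p))
    Hn <- if (k_universe > 1L) H / log(k_universe) else 0
    Hn * length(nb) / nV
  }, 0)
  stats::setNames(fh, nodes)
}

#' Hierarchy disruption between two conditions
#'
#' The distributional part is the 1-D order-1 Wasserstein distance between
#' the two FH score distributions (no shared genes needed). The gene-level
#' part takes, over shared genes, the differences `d = fh_right - fh_left`
#' and flags genes with `|d - mean(d)| > 2 sd(d)` as disrupted; with zero
#' spread no gene is flagged.
#'
#' @param fh_left,fh_right Named FH score vectors for the two conditions.
#' @return List with `wasserstein`, `disrupted` (character vector) and
#'   `n_shared`.
#' @export
hierarchy_disruption <- function(fh_left, fh_right) {
  wd <- wasserstein_1d(fh_left, fh_right)
  shared <- intersect(names(fh_left), names(fh_right))
  disrupted <- character(0)
  if (length(shared) >= 3L) {
    d <- fh_right[shared] - fh_left[shared]
    s <- stats::sd(d)
    if (s > 0) disrupted <- shared[abs(d - mean(d)) > 2 * s]
  }
  list(wasserstein = wd, disrupted = disrupted, n_shared = length(shared))
}

#' One-dimensional order-1 Wasserstein distance
#'
#' Computed as the integral of the absolute difference of the two
#' empirical quantile (equivalently, distribution) functions; for
#' equal-size samples this reduces to the mean absolute difference of the
#' sorted values.
#'
#' @param a,b Nonempty numeric samples (any sizes).
#' @return Nonnegative distance.
#' @export
wasserstein_1d <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  breaks <- sort(c(a, b))
  n <- length(breaks)
  if (n < 2L) return(0)
  pts <- breaks[-n]
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  sum(abs(Fa - Fb) * diff(breaks))
}

#' Permutation p-value for the Wasserstein distance
#'
#' Pools the two samples, reshuffles the labels `B` times, and reports
#' `p = (1 + #{permuted distance >= observed}) / (1 + B)`, so the smallest
#' attainable p is `1 / (B + 1)`.
#'
#' @param a,b Numeric samples.
#' @param B Number of permutations (>= 99).
#' @param seed Optional integer seed for the label shuffling.
#' @return List with `statistic` (observed distance) and `p`.
#' @export
wasserstein_permutation_p <- function(a, b, B = 9999L, seed = NULL) {
  stopifnot(B >= 99L)
  if (!is.null(seed)) set.seed(seed)
  obs <- wasserstein_1d(a, b)
  pool <- c(a, b)
  na <- length(a)
  exceed <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(length(pool), na)
    d <- wasserstein_1d(pool[idx], pool[-idx])
    if (d >= obs) exceed <- exceed + 1L
  }
  list(statistic = obs, p = (1 + exceed) / (1 + B))
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] returning the Welch statistic,
#' Welch-Satterthwaite degrees of freedom and two-sided p-value.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("welch_t: both samples have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Outlier-resistant k-means clustering of influence trajectories
#'
#' Genes whose total trajectory mass is extreme under a robust
#' (median/MAD) z-score are set aside as outliers. The remaining
#' trajectories are normalized per gene by their maximum and clustered
#' with k-means (fixed seed, multiple restarts) for each k in `k_range`;
#' the k with the highest mean silhouette width is kept. Outliers are
#' labeled `"OUTLIER"` and also assigned post hoc to the nearest centroid
#' for reporting.
#'
#' @param trajectory A `dynafic_trajectory` or genes x time matrix.
#' @param k_range Candidate cluster counts (default 2:6); shrunk
#'   automatically when there are few genes.
#' @param seed Integer seed making the clustering deterministic.
#' @param outlier_z Robust z threshold (default 3.5, the conventional
#'   modified-z cutoff).
#' @param restarts Number of k-means restarts (default 50).
#' @return List of class `dynafic_clusters` with `labels` (gene ->
#'   cluster id as character, or `"OUTLIER"`), `k`, `silhouette`,
#'   `centroids`, `outliers`, `outlier_assignment`, `degenerate`.
#' @export
cluster_trajectories <- function(trajectory, k_range = 2:6, seed = 1L,
                                 outlier_z = 3.5, restarts = 50L) {
  X <- if (inherits(trajectory, "dynafic_trajectory")) trajectory$X else trajectory
  genes <- rownames(X)
  mass <- rowSums(X)
  dev <- abs(mass - stats::median(mass))
  madv <- stats::mad(mass, constant = 1)
  z <- if (madv > 0) {
    0.6745 * dev / madv
  } else if (mean(dev) > 0) {
    0.7979 * dev / mean(dev)  # mean-AD fallback when MAD degenerates
  } else {
    dev * 0
  }
  outliers <- genes[z > outlier_z]
  core <- setdiff(genes, outliers)
  if (length(core) < 3L) {
    stop("cluster_trajectories: fewer than 3 non-outlier genes")
  }
  norm_rows <- function(M) {
    mx <- apply(M, 1L, max)
    mx[mx == 0] <- 1
    M / mx
  }
  Xn <- norm_rows(X[core, , drop = FALSE])
  k_range <- k_range[k_range >= 2L & k_range <= length(core) - 1L]
  if (!length(k_range)) k_range <- 2L
  dmat <- stats::dist(Xn)
  degenerate <- max(dmat) == 0
  if (degenerate) {
    labels <- stats::setNames(rep("1", length(genes)), genes)
    labels[outliers] <- "OUTLIER"
    return(structure(list(labels = labels, k = min(k_range),
                          silhouette = NA_real_,
                          centroids = matrix(colMeans(Xn), nrow = 1L,
                                             dimnames = list("1", colnames(X))),
                          outliers = outliers,
                          outlier_assignment = stats::setNames(
                            rep("1", length(outliers)), outliers),
                          degenerate = TRUE),
                     class = "dynafic_clusters"))
  }
  set.seed(seed)
  best <- NULL
  for (k in k_range) {
    km <- stats::kmeans(Xn, centers = k, nstart = restarts, iter.max = 100L)
    sil <- mean(cluster::silhouette(km$cluster, dmat)[, 3L])
    if (is.null(best) || sil > best$sil) {
      best <- list(km = km, sil = sil, k = k)
    }
  }
  labels <- stats::setNames(as.character(best$km$cluster), core)
  full <- stats::setNames(rep(NA_character_, length(genes)), genes)
  full[core] <- labels
  full[outliers] <- "OUTLIER"
  assign_out <- stats::setNames(character(0), character(0))
  if (length(outliers)) {
    Xo <- norm_rows(X[outliers, , drop = FALSE])
    assign_out <- stats::setNames(vapply(seq_along(outliers), function(i) {
      d2 <- colSums((t(best$km$centers) - Xo[i, ])^2)
      as.character(which.min(d2))
    }, ""), outliers)
  }
  structure(list(labels = full, k = best$k, silhouette = best$sil,
                 centroids = best$km$centers, outliers = outliers,
                 outlier_assignment = assign_out, degenerate = FALSE),
            class = "dynafic_clusters")
}

#' @export
print.dynafic_clusters <- function(x, ...) {
  cat(sprintf("Trajectory clustering: k = %d, mean silhouette = %s, %d outlier(s)%s\n",
              x$k, format(x$silhouette, digits = 3), length(x$outliers),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pearson correlation between expression magnitude and scaled score
#'
#' @param de DE data.frame (`gene`, `log2fc`).
#' @param scores Score table from [score_table()] (or any data.frame with
#'   `gene` and `dynafic_scaled`).
#' @return Pearson r over the shared genes.
#' @export
expression_influence_correlation <- function(de, scores) {
  shared <- intersect(de$gene, scores$gene)
  if (length(shared) < 3L) {
    stop("expression_influence_correlation: need at least 3 shared genes")
  }
  x <- abs(de$log2fc[match(shared, de$gene)])
  y <- scores$dynafic_scaled[match(shared, scores$gene)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("expression_influence_correlation: zero variance")
  }
  stats::cor(x, y)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the actual overlap between a selected
#' gene set and a special (e.g. tissue-specific) gene set within a finite
#' universe.
#'
#' @param selected,special Gene sets (subsets of `universe`).
#' @param universe Background gene set (nonempty).
#' @return p-value in (0, 1].
#' @export
hypergeom_enrichment <- function(selected, special, universe) {
  if (!length(universe)) stop("hypergeom_enrichment: empty universe")
  selected <- unique(selected); special <- unique(special)
  universe <- unique(universe)
  stopifnot(all(selected %in% universe), all(special %in% universe))
  k <- length(intersect(selected, special))
  stats::phyper(k - 1L, length(special),
                length(universe) - length(special), length(selected),
                lower.tail = FALSE)
}

#' Spearman agreement between full and PPI-only score rankings
#'
#' @param scores_full,scores_ppi_only Score tables (or named numeric
#'   vectors of raw scores) from two runs on the same gene universe.
#' @return Spearman rank correlation over the shared genes.
#' @export
ablation_compare <- function(scores_full, scores_ppi_only) {
  as_vec <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$dynafic_raw, s$gene) else s
  }
  a <- as_vec(scores_full); b <- as_vec(scores_ppi_only)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    stop("ablation_compare: fewer than 3 shared genes")
  }
  stats::cor(a[shared], b[shared], method = "spearman")
}

#' Set arithmetic between two DE gene lists
#'
#' Quantifies how a covariate-adjusted model reshapes a simple model's
#' gene list: genes lost (with percentage of the simple list), genes
#' gained, genes shared, and the Jaccard overlap percentage.
#'
#' @param set_simple,set_adjusted Nonempty character vectors.
#' @return List with `lost_n`, `lost_pct`, `gained_n`, `shared_n`,
#'   `jaccard_pct`.
#' @export
set_comparison_stats <- function(set_simple, set_adjusted) {
  stopifnot(length(set_simple) >= 1L, length(set_adjusted) >= 1L)
  set_simple <- unique(set_simple); set_adjusted <- unique(set_adjusted)
  lost <- setdiff(set_simple, set_adjusted)
  gained <- setdiff(set_adjusted, set_simple)
  shared <- intersect(set_simple, set_adjusted)
  list(
    lost_n = length(lost),
    lost_pct = 100 * length(lost) / length(set_simple),
    gained_n = length(gained),
    shared_n = length(shared),
    jaccard_pct = 100 * length(shared) /
      length(union(set_simple, set_adjusted))
  )
}

#' Two-group proportion comparison
#'
#' Percentages (rounded to one decimal, as conventionally printed) and a
#' 2x2 chi-square test without continuity correction; Fisher's exact test
#' is available via `exact = TRUE`.
#'
#' @param a_pos,a_n Positives and total in group A.
#' @param b_pos,b_n Positives and total in group B.
#' @param exact Use Fisher's exact test instead of chi-square.
#' @return List with `pct_a`, `pct_b`, `chi2_p`.
#' @export
contingency_props <- function(a_pos, a_n, b_pos, b_n, exact = FALSE) {
  stopifnot(a_n > 0, b_n > 0, a_pos <= a_n, b_pos <= b_n,
            a_pos >= 0, b_pos >= 0)
  tab <- matrix(c(a_pos, a_n - a_pos, b_pos, b_n - b_pos), nrow = 2L,
                byrow = TRUE)
  p <- if (exact) {
    stats::fisher.test(tab)$p.value
  } else if (a_pos / a_n == b_pos / b_n) {
    1  # identical proportions: statistic is exactly 0
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(pct_a = round(100 * a_pos / a_n, 1L),
       pct_b = round(100 * b_pos / b_n, 1L),
       chi2_p = p)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Convenience wrapper over [stats::p.adjust()]; no correction is applied
#' by default anywhere in the comparison analytics.
#'
#' @param p Numeric vector of p-values.
#' @return BH-adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
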