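# Multi-layer network integration: combine PPI, TF and GO edge layers into
# one weighted adjacency and the row-stochastic propagation matrix.

#' Integrate edge layers into a multi-layer network
#'
#' The node set is the union of all edge endpoints plus any extra `nodes`
#' (isolated genes stay in the network). Pair weights sum
#' `layer_weight * edge_weight` over the layers containing the pair;
#' undirected layers (PPI, GO) contribute symmetrically while TF edges
#' contribute only in the source-to-target direction. The propagation
#' matrix `W` is the row-normalized combined adjacency; rows with no
#' outgoing weight receive a unit self-loop so `W` stays row-stochastic.
#' Node order is lexicographic and fixed before any matrix is built.
#'
#' @param ppi,tf,go Edge data.frames from the layer readers/builders; any
#'   may be `NULL` or empty.
#' @param layer_weights Named numeric vector (`ppi`, `go`, `tf`), default
#'   1.0 / 0.5 / 1.5.
#' @param nodes Optional extra gene symbols to include as nodes.
#' @return Object of class `dynafic_network`: list with `nodes`, `layers`,
#'   `A` (combined weight matrix, sparse), `W` (row-stochastic), and
#'   `tf_outdeg` (named vector over all nodes).
#' @export
integrate_layers <- function(ppi = NULL, tf = NULL, go = NULL,
                             layer_weights = c(ppi = 1.0, go = 0.5,
                                               tf = 1.5),
                             nodes = NULL) {
  layers <- list(ppi = ppi, tf = tf, go = go)
  layers <- lapply(layers, function(e) {
    if (is.null(e)) edge_frame(character(0), character(0), "ppi",
                               numeric(0), FALSE) else e
  })
  endpoints <- unlist(lapply(layers, function(e) c(e$source, e$target)),
                      use.names = FALSE)
  all_nodes <- sort(unique(c(endpoints, nodes)))
  if (!length(all_nodes)) stop("integrate_layers: empty node set")
  n <- length(all_nodes)
  idx <- stats::setNames(seq_len(n), all_nodes)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(e, w_layer, symmetric) {
    if (!nrow(e)) return()
    i <- idx[e$source]; j <- idx[e$target]; x <- w_layer * e$weight
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
    if (symmetric) {
      ii <<- c(ii, j); jj <<- c(jj, i); xx <<- c(xx, x)
    }
  }
  add(layers$ppi, layer_weights[["ppi"]], symmetric = TRUE)
  add(layers$go, layer_weights[["go"]], symmetric = TRUE)
  add(layers$tf, layer_weights[["tf"]], symmetric = FALSE)

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(all_nodes, all_nodes))
  rs <- Matrix::rowSums(A)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(n, x = scale) %*% A
  if (any(rs == 0)) {
    loop <- which(rs == 0)
    W <- W + Matrix::sparseMatrix(i = loop, j = loop,
                                  x = rep(1, length(loop)),
                                  dims = c(n, n))
  }
  dimnames(W) <- list(all_nodes, all_nodes)
  outdeg <- stats::setNames(rep(0L, n), all_nodes)
  if (nrow(layers$tf)) {
    tab <- table(layers$tf$source)
    outdeg[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = all_nodes, layers = layers, A = A, W = W,
                 tf_outdeg = outdeg),
            class = "dynafic_network")
}

#' @export
print.dynafic_network <- function(x, ...) {
  cat(sprintf("Multi-layer network: %d nodes; edges ppi = %d, tf = %d, go = %d\n",
              length(x$nodes), nrow(x$layers$ppi), nrow(x$layers$tf),
              nrow(x$layers$go)))
  invisible(x)
}

#' Normalized degree centrality on the combined undirected view
#'
#' A pair counts as adjacent when it carries weight in any layer; TF edge
#' direction is ignored and multi-layer pairs count once. Centrality is
#' degree divided by (n - 1), hence in [0, 1].
#'
#' @param network A `dynafic_network`.
#' @return Named numeric vector over the network nodes.
#' @export
degree_centrality <- function(network) {
  n <- length(network$nodes)
  if (n < 2L) stop("degree_centrality: need at least two nodes")
  U <- network$A + Matrix::t(network$A)
  Matrix::diag(U) <- 0
  deg <- Matrix::rowSums(U > 0)
  stats::setNames(as.numeric(deg) / (n - 1L), network$nodes)
}

#' Cross-layer edge-metric correlation table
#'
#' For every gene pair carrying weight in at least one layer, assembles the
#' triplet (PPI weight, GO similarity, TF regulatory strength) with absent
#' layers imputed as 0, and returns the 3x3 Pearson correlation matrix.
#' When annotations and an ontology are supplied, GO similarity is the
#' actual (unthresholded) best-match-average similarity of the pair;
#' otherwise the thresholded GO-layer edge weight is used.
#'
#' @param network A `dynafic_network`.
#' @param annotations Optional named list gene -> term ids.
#' @param dag Optional `dynafic_ontology`.
#' @return List with `r` (3x3 correlation matrix over ppi/go/tf),
#'   `n_pairs`, and `degenerate` (TRUE when any metric has zero variance;
#'   the corresponding correlations are `NA`).
#' @export
edge_metric_correlations <- function(network, annotations = NULL,
                                     dag = NULL) {
  pair_key <- function(e, drop_dir = FALSE) {
    if (!nrow(e)) return(character(0))
    a <- pmin(e$source, e$target); b <- pmax(e$source, e$target)
    paste(a, b, sep = "\r")
  }
  keys <- unique(c(pair_key(network$layers$ppi),
                   pair_key(network$layers$tf),
                   pair_key(network$layers$go)))
  if (length(keys) < 3L) {
    stop("edge_metric_correlations: need at least 3 gene pairs")
  }
  layer_vec <- function(e) {
    v <- stats::setNames(rep(0, length(keys)), keys)
    if (nrow(e)) {
      k <- pair_key(e)
      agg <- tapply(e$weight, k, max)
      v[names(agg)] <- as.numeric(agg)
    }
    v
  }
  ppi_w <- layer_vec(network$layers$ppi)
  tf_w <- layer_vec(network$layers$tf)
  if (!is.null(annotations) && !is.null(dag)) {
    genes <- strsplit(keys, "\r", fixed = TRUE)
    all_terms <- unique(unlist(annotations, use.names = FALSE))
    all_terms <- all_terms[all_terms %in% dag$terms]
    M <- if (length(all_terms)) term_similarity_matrix(all_terms, dag) else NULL
    go_w <- vapply(genes, function(p) {
      s <- gene_functional_similarity(p[1L], p[2L], annotations, dag,
                                      term_sim = M)
      if (is.na(s)) 0 else s
    }, 0)
  } else {
    go_w <- layer_vec(network$layers$go)
  }
  X <- cbind(ppi = ppi_w, go = go_w, tf = tf_w)
  degenerate <- any(apply(X, 2L, stats::sd) == 0)
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  list(r = r, n_pairs = length(keys), degenerate = degenerate)
}
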