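# Discrete-time influence diffusion: initial vector construction,
# regulatory amplification, and the propagation iteration.

#' Tissue-specificity weights from a median-expression table
#'
#' Weights emphasize genes expressed above the tissue median:
#' `w = max(0, tanh((e - median) / (IQR + 1e-9)))`, so at-median and
#' below-median genes get 0 and strongly above-median genes approach 1.
#' Genes absent from the table default to weight 0 downstream.
#'
#' @param expr Data.frame with columns `gene`, `expr` (see
#'   [read_expression()]).
#' @return Named numeric vector of weights in [0, 1).
#' @export
tissue_weight <- function(expr) {
  stopifnot(nrow(expr) >= 2L)
  e <- expr$expr
  m <- stats::median(e)
  iqr <- stats::IQR(e)
  if (iqr == 0) {
    warning("tissue_weight: all expression values equal; all weights 0")
  }
  w <- pmax(0, tanh((e - m) / (iqr + 1e-9)))
  stats::setNames(w, expr$gene)
}

#' Initial influence vector from differential expression
#'
#' Each gene's raw influence is the product of its fold-change magnitude,
#' its statistical significance (`-log10(padj + 1e-300)`, capped at 50 so
#' numerically-zero adjusted p-values cannot dominate), and an affine
#' tissue factor `0.5 + 0.5 * w` that halves rather than zeroes
#' tissue-silent genes. The vector is normalized to sum to 1.
#'
#' @param de Differential-expression data.frame (`gene`, `log2fc`, `padj`).
#' @param w Named tissue weights from [tissue_weight()]; genes absent get 0.
#' @return Named numeric vector `x0` summing to 1.
#' @export
initial_influence <- function(de, w = NULL) {
  stopifnot(nrow(de) >= 1L)
  wg <- rep(0, nrow(de))
  if (!is.null(w)) {
    hit <- de$gene %in% names(w)
    wg[hit] <- w[de$gene[hit]]
  }
  sig <- pmin(-log10(de$padj + 1e-300), 50)
  raw <- abs(de$log2fc) * sig * (0.5 + 0.5 * wg)
  if (sum(raw) == 0) {
    stop("initial_influence: no usable signal (all raw influences are 0)")
  }
  stats::setNames(raw / sum(raw), de$gene)
}

#' Regulatory amplification operator
#'
#' Diagonal multiplier boosting transcription factors in proportion to
#' their out-degree in the TF layer:
#' `d_i = 1 + outdeg(i) / max(outdeg)` when the network has TF edges
#' (so the top regulator gets a factor of exactly 2), identity otherwise.
#'
#' @param network A `dynafic_network`.
#' @return Named numeric vector of multipliers >= 1 over all nodes.
#' @export
amplification_operator <- function(network) {
  od <- network$tf_outdeg
  mx <- max(od)
  if (mx > 0) 1 + od / mx else od * 0 + 1
}

#' Propagate influence through the network
#'
#' Iterates `y = gamma * x(t) + (1 - gamma) * t(W) (D x(t))` for `T` steps,
#' where `W` is the row-stochastic combined adjacency (the transpose makes
#' influence flow from edge sources to targets) and `D` the amplification
#' operator. After each step the vector is rescaled to its previous total,
#' so mass is conserved exactly; with `D = I` the rescaling is a no-op up
#' to machine precision because `t(W)` of a row-stochastic matrix is
#' column-stochastic.
#'
#' @param x0 Named initial influence vector (sums to 1); genes missing
#'   from the network raise an error, network nodes missing from `x0`
#'   start at 0.
#' @param network A `dynafic_network`.
#' @param D Amplification vector from [amplification_operator()]; `NULL`
#'   for the identity.
#' @param gamma Retention in (0, 1].
#' @param T Number of steps (>= 1).
#' @return Object of class `dynafic_trajectory`: list with `genes`, `X`
#'   (genes x (T+1) matrix, columns `t0` ... `tT`) and `params`.
#' @export
propagate <- function(x0, network, D = NULL, gamma = 0.7, T = 5L) {
  stopifnot(gamma > 0, gamma <= 1, T >= 1L)
  nodes <- network$nodes
  missing <- setdiff(names(x0), nodes)
  if (length(missing)) {
    stop("propagate: genes absent from the network: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- stats::setNames(rep(0, length(nodes)), nodes)
  x[names(x0)] <- x0
  if (is.null(D)) D <- stats::setNames(rep(1, length(nodes)), nodes)
  if (length(D) != length(nodes)) {
    stop("propagate: amplification operator dimension mismatch")
  }
  D <- D[nodes]
  Wt <- Matrix::t(network$W)
  X <- matrix(0, nrow = length(nodes), ncol = T + 1L,
              dimnames = list(nodes, paste0("t", 0:T)))
  X[, 1L] <- x
  for (step in seq_len(T)) {
    y <- gamma * x + (1 - gamma) * as.numeric(Wt %*% (D * x))
    x <- y * (sum(x) / sum(y))
    X[, step + 1L] <- x
  }
  structure(list(genes = nodes, X = X,
                 params = list(gamma = gamma, T = T,
                               renormalized = TRUE)),
            class = "dynafic_trajectory")
}

#' @export
print.dynafic_trajectory <- function(x, ...) {
  cat(sprintf("Influence trajectory: %d genes x %d time points (gamma = %g)\n",
              nrow(x$X), ncol(x$X), x$params$gamma))
  invisible(x)
}
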