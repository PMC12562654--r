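# Readers for the external text formats. Every parser is strict: malformed
# numeric cells raise an error naming the line rather than becoming NA.

# Sniff the delimiter from the header line: tab wins over comma over
# generic whitespace. Header row is mandatory in all formats.
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

read_delim_chr <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

# Strict numeric conversion; `line` offsets are data-row indices (header = 1).
parse_numeric_strict <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in column '%s' of %s (line %d)",
                 x[bad[1L]], column, path, bad[1L] + 1L))
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop(sprintf("missing value in column '%s' of %s (line %d)",
                 column, path, bad[1L] + 1L))
  }
  out
}

match_column <- function(df, aliases, what, path) {
  hit <- which(tolower(names(df)) %in% tolower(aliases))
  if (!length(hit)) {
    stop(sprintf("%s: missing required column '%s' (accepted names: %s)",
                 path, what, paste(aliases, collapse = ", ")))
  }
  hit[1L]
}

#' Read and filter a differential-expression table
#'
#' Reads a delimited table (comma or tab, auto-detected; header mandatory)
#' with gene symbol, log2 fold change, raw p and BH-adjusted p columns.
#' Column names are matched case-insensitively against common aliases.
#' Duplicate gene symbols are collapsed to the row with the smallest
#' adjusted p before filtering; rows are kept when `padj < padj_max` and
#' `|log2fc| > abs_lfc_min` (both strict, matching the printed thresholds
#' adjusted p < 0.05 and |log2FC| > 0.58, i.e. 1.5-fold).
#'
#' @param path Path to a CSV/TSV file.
#' @param padj_max,abs_lfc_min Filter thresholds (strict inequalities).
#' @return A data.frame with columns `gene`, `log2fc`, `pvalue`, `padj`,
#'   in the input row order of the surviving records.
#' @export
read_de_table <- function(path, padj_max = 0.05, abs_lfc_min = 0.58) {
  df <- read_delim_chr(path)
  ig <- match_column(df, c("gene", "symbol", "gene_symbol", "genes"),
                     "gene", path)
  il <- match_column(df, c("log2fc", "log2foldchange", "logfc", "lfc"),
                     "log2fc", path)
  ip <- match_column(df, c("p", "pvalue", "p.value", "pval"), "pvalue", path)
  ia <- match_column(df, c("padj", "adj.p.val", "fdr", "qvalue", "padjust"),
                     "padj", path)
  out <- data.frame(
    gene = df[[ig]],
    log2fc = parse_numeric_strict(df[[il]], names(df)[il], path),
    pvalue = parse_numeric_strict(df[[ip]], names(df)[ip], path),
    padj = parse_numeric_strict(df[[ia]], names(df)[ia], path),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$gene))) stop(path, ": empty gene symbol")
  if (any(out$pvalue < 0 | out$pvalue > 1)) {
    stop(path, ": p-value outside [0, 1]")
  }
  if (any(out$padj < 0 | out$padj > 1)) {
    stop(path, ": adjusted p-value outside [0, 1]")
  }
  if (anyDuplicated(out$gene)) {
    n0 <- nrow(out)
    keep <- unlist(lapply(split(seq_len(n0), out$gene), function(idx) {
      idx[which.min(out$padj[idx])]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    message(sprintf("read_de_table: collapsed %d duplicate gene row(s)",
                    n0 - nrow(out)))
  }
  out <- out[out$padj < padj_max & abs(out$log2fc) > abs_lfc_min, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a STRING-style protein-protein interaction edge list
#'
#' Expects columns `protein1`, `protein2`, `combined_score` (0-1000 scale;
#' whitespace- or tab-delimited, header mandatory). Rows with
#' `combined_score >= min_score` are kept and rescaled to weights in (0, 1]
#' by division by 1000. Self-loops are dropped, pairs are stored with
#' `source < target` lexicographically, and duplicate pairs keep the
#' maximum weight.
#'
#' @param path Path to the edge list.
#' @param min_score Integer score floor on the 0-1000 scale (inclusive).
#' @return Edge data.frame with columns `source`, `target`, `layer`
#'   (`"ppi"`), `weight`, `directed` (FALSE).
#' @export
read_ppi_edges <- function(path, min_score = 400L) {
  df <- read_delim_chr(path)
  i1 <- match_column(df, c("protein1", "source", "gene1"), "protein1", path)
  i2 <- match_column(df, c("protein2", "target", "gene2"), "protein2", path)
  is <- match_column(df, c("combined_score", "score"), "combined_score", path)
  score <- parse_numeric_strict(df[[is]], names(df)[is], path)
  if (any(score < 0 | score > 1000)) {
    bad <- which(score < 0 | score > 1000)[1L]
    stop(sprintf("%s: combined_score %g outside [0, 1000] (line %d)",
                 path, score[bad], bad + 1L))
  }
  keep <- score >= min_score & df[[i1]] != df[[i2]]
  a <- df[[i1]][keep]; b <- df[[i2]][keep]; w <- score[keep] / 1000
  src <- pmin(a, b); tgt <- pmax(a, b)
  edges <- data.frame(source = src, target = tgt, weight = w,
                      stringsAsFactors = FALSE)
  edges <- dedupe_edges(edges, combine = max)
  edge_frame(edges$source, edges$target, "ppi", edges$weight, FALSE)
}

# Canonical edge-record data.frame; safe for zero rows.
edge_frame <- function(source, target, layer, weight, directed) {
  n <- length(source)
  data.frame(source = as.character(source), target = as.character(target),
             layer = rep_len(layer, n), weight = as.numeric(weight),
             directed = rep_len(directed, n), stringsAsFactors = FALSE)
}

dedupe_edges <- function(edges, combine = max) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$source, edges$target, sep = "\r")
  w <- tapply(edges$weight, key, combine)
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$weight <- as.numeric(w[paste(out$source, out$target, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Read a TRRUST-style directed regulator-target edge list
#'
#' Expects a TSV with a header whose first two columns are the transcription
#' factor and its target (any further columns such as regulation mode or
#' PMIDs are ignored). Edges are directed with weight 1; duplicates are
#' collapsed and self-loops dropped.
#'
#' @param path Path to the TSV file.
#' @return Edge data.frame with columns `source`, `target`, `layer`
#'   (`"tf"`), `weight` (1), `directed` (TRUE).
#' @export
read_tf_edges <- function(path) {
  df <- read_delim_chr(path)
  i1 <- match_column(df, c("tf", "source", "regulator"), "TF", path)
  i2 <- match_column(df, c("target", "gene"), "target", path)
  a <- df[[i1]]; b <- df[[i2]]
  keep <- a != b
  edges <- unique(data.frame(source = a[keep], target = b[keep],
                             stringsAsFactors = FALSE))
  if (!nrow(edges)) warning("read_tf_edges: no regulatory edges in ", path)
  rownames(edges) <- NULL
  edge_frame(edges$source, edges$target, "tf", rep(1.0, nrow(edges)), TRUE)
}

#' Read a two-column tissue expression table
#'
#' GTEx-style gene / median-expression pairs (TSV or CSV, header mandatory).
#' Negative expression values are a parse error; duplicate genes are
#' averaged with a message.
#'
#' @param path Path to the table.
#' @return Data.frame with columns `gene`, `expr`.
#' @export
read_expression <- function(path) {
  df <- read_delim_chr(path)
  if (ncol(df) < 2L) stop(path, ": expected two columns (gene, expression)")
  expr <- parse_numeric_strict(df[[2L]], names(df)[2L], path)
  if (any(expr < 0)) {
    bad <- which(expr < 0)[1L]
    stop(sprintf("%s: negative expression %g (line %d)", path,
                 expr[bad], bad + 1L))
  }
  gene <- df[[1L]]
  if (anyDuplicated(gene)) {
    expr <- as.numeric(tapply(expr, gene, mean)[unique(gene)])
    message("read_expression: averaged duplicate gene rows")
    gene <- unique(gene)
  }
  data.frame(gene = gene, expr = expr, stringsAsFactors = FALSE)
}

#' Read a gene-to-term annotation map
#'
#' Two-column TSV (gene, term; header mandatory). Terms absent from the
#' ontology are dropped with a message reporting the count; genes left with
#' no valid terms are removed.
#'
#' @param path Path to the annotation table.
#' @param dag An ontology DAG from [read_ontology()].
#' @return Named list mapping gene symbol to a character vector of term ids.
#' @export
read_annotations <- function(path, dag) {
  df <- read_delim_chr(path)
  if (ncol(df) < 2L) stop(path, ": expected two columns (gene, term)")
  gene <- df[[1L]]; term <- df[[2L]]
  known <- term %in% dag$terms
  if (any(!known)) {
    message(sprintf("read_annotations: dropped %d annotation(s) with terms absent from the ontology",
                    sum(!known)))
  }
  gene <- gene[known]; term <- term[known]
  ann <- lapply(split(term, gene), unique)
  ann[lengths(ann) > 0L]
}
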