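# Writers for the package's TSV outputs and the JSON run manifest.

#' Write / read a weighted edge list
#'
#' `write_edges()` serializes an edge data.frame (columns source, target,
#' layer, weight, directed) as TSV; `read_edges()` reads it back. Writing
#' then re-reading reproduces the edge set exactly (order-insensitive).
#'
#' @param edges Edge data.frame as produced by the layer readers.
#' @param path Output path.
#' @return `write_edges()` returns `path` invisibly; `read_edges()` returns
#'   the edge data.frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "character"),
                          stringsAsFactors = FALSE)
  edge_frame(df$source, df$target, df$layer,
             parse_numeric_strict(df$weight, "weight", path),
             as.logical(df$directed))
}

#' Write an influence trajectory as TSV
#'
#' One row per gene with columns `gene`, `t0` ... `tT`.
#'
#' @param trajectory A `dynafic_trajectory` object.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  X <- trajectory$X
  df <- data.frame(gene = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration snapshot, input file MD5 hashes, seed, package
#' version and per-stage timings, so a run can be reproduced exactly.
#'
#' @param path Output path for the JSON file.
#' @param config A `dynafic_config`.
#' @param inputs Named character vector of input file paths (hashed).
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @param extra Named list of additional fields (e.g. dropped-record
#'   counts, design-decision flags).
#' @export
write_manifest <- function(path, config, inputs = character(0),
                           timings = numeric(0), extra = list()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  cfg <- unclass(config)
  cfg$layer_weights <- as.list(cfg$layer_weights)  # keep names in JSON
  manifest <- c(list(
    package = "dynafic",
    version = as.character(utils::packageVersion("dynafic")),
    config = cfg,
    inputs = as.list(inputs),
    input_md5 = hashes,
    timings_sec = as.list(timings),
    flags = list(
      diffusion_operator = "transpose(W), renormalized per step",
      term_set_combination = "best-match average",
      log_transform = "log1p",
      depth_rule = "longest path to root"
    )
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
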