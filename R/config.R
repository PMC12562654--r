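#' Run configuration for the DynaFIC pipeline
#'
#' Bundles every tunable parameter of the framework with its default value.
#' Defaults follow the published parameterization: retention `gamma = 0.7`
#' over `T = 5` diffusion steps, score weights `omega1 = 0.8` and
#' `omega2 = 0.4`, context-modulation scaling `theta1 = 2` and
#' `theta2 = 0.1`, layer weights 1.0 (PPI), 0.5 (GO), 1.5 (TF), a STRING
#' combined-score floor of 400 (0-1000 scale), a GO-similarity threshold of
#' 0.3 (strict `>`), and differential-expression thresholds adjusted
#' p < 0.05 with |log2 fold change| > 0.58.
#'
#' @param gamma Influence retention per diffusion step, in (0, 1].
#' @param T Number of diffusion steps (integer >= 1).
#' @param omega1,omega2 Nonnegative weights of the influence and centrality
#'   components of the composite score.
#' @param theta1,theta2 Scaling parameters of the context modulation index.
#' @param layer_weights Named numeric vector with entries `ppi`, `go`, `tf`.
#' @param ppi_min_score Minimum STRING-style combined score (0-1000 scale).
#' @param go_sim_threshold GO-layer similarity threshold in [0, 1]; edges
#'   require similarity strictly above it.
#' @param de_padj_max,de_abs_lfc_min Differential-expression filters:
#'   adjusted p strictly below `de_padj_max` and |log2FC| strictly above
#'   `de_abs_lfc_min`.
#' @param seed Integer seed recorded in the manifest and used wherever the
#'   pipeline draws random numbers.
#' @param permutations Number of label permutations for the Wasserstein null.
#' @return An object of class `dynafic_config` (a named list).
#' @examples
#' cfg <- dynafic_config()
#' cfg$gamma
#' @export
dynafic_config <- function(gamma = 0.7,
                           T = 5L,
                           omega1 = 0.8,
                           omega2 = 0.4,
                           theta1 = 2,
                           theta2 = 0.1,
                           layer_weights = c(ppi = 1.0, go = 0.5, tf = 1.5),
                           ppi_min_score = 400L,
                           go_sim_threshold = 0.3,
                           de_padj_max = 0.05,
                           de_abs_lfc_min = 0.58,
                           seed = 1L,
                           permutations = 9999L) {
  cfg <- list(
    gamma = gamma, T = as.integer(T),
    omega1 = omega1, omega2 = omega2,
    theta1 = theta1, theta2 = theta2,
    layer_weights = layer_weights,
    ppi_min_score = as.integer(ppi_min_score),
    go_sim_threshold = go_sim_threshold,
    de_padj_max = de_padj_max,
    de_abs_lfc_min = de_abs_lfc_min,
    seed = as.integer(seed),
    permutations = as.integer(permutations)
  )
  class(cfg) <- "dynafic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$gamma), length(cfg$gamma) == 1L,
    cfg$gamma > 0, cfg$gamma <= 1,
    cfg$T >= 1L,
    cfg$omega1 >= 0, cfg$omega2 >= 0,
    cfg$go_sim_threshold >= 0, cfg$go_sim_threshold <= 1,
    cfg$permutations >= 1L
  )
  need <- c("ppi", "go", "tf")
  if (!all(need %in% names(cfg$layer_weights))) {
    stop("layer_weights must name ", paste(need, collapse = ", "))
  }
  if (any(cfg$layer_weights < 0)) stop("layer weights must be nonnegative")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; keys absent from the file keep their defaults,
#' so a config file only needs to name the parameters it overrides.
#'
#' @param path Path to a YAML file whose keys match [dynafic_config()]
#'   arguments (`layer_weights` as a mapping with keys ppi/go/tf).
#' @return A `dynafic_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(dynafic_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$layer_weights)) {
    raw$layer_weights <- unlist(raw$layer_weights)
  }
  do.call(dynafic_config, raw)
}

#' @export
print.dynafic_config <- function(x, ...) {
  cat("DynaFIC run configuration\n")
  cat(sprintf("  diffusion: gamma = %g, T = %d\n", x$gamma, x$T))
  cat(sprintf("  score weights: omega1 = %g, omega2 = %g\n", x$omega1, x$omega2))
  cat(sprintf("  context scaling: theta1 = %g, theta2 = %g\n", x$theta1, x$theta2))
  cat(sprintf("  layer weights: ppi = %g, go = %g, tf = %g\n",
              x$layer_weights[["ppi"]], x$layer_weights[["go"]],
              x$layer_weights[["tf"]]))
  cat(sprintf("  filters: combined_score >= %d, GO sim > %g, padj < %g, |log2FC| > %g\n",
              x$ppi_min_score, x$go_sim_threshold, x$de_padj_max,
              x$de_abs_lfc_min))
  cat(sprintf("  seed = %d, permutations = %d\n", x$seed, x$permutations))
  invisible(x)
}
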