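# Shared fixtures: tiny ontologies, file writers and brute-force oracles
# used across the suite. Everything is built in code at test time.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  path
}

# chain ontology root <- A <- B
chain_dag <- function() {
  ontology_from_parents(list(
    root = character(0),
    A = c(root = "is_a"),
    B = c(A = "is_a")
  ))
}

# 4-term DAG: root <- A <- B, root <- C
toy_dag <- function() {
  ontology_from_parents(list(
    root = character(0),
    A = c(root = "is_a"),
    B = c(A = "is_a"),
    C = c(root = "is_a")
  ))
}

# diamond: root <- X <- D, root <- Y <- Z <- D (two paths to root for D,
# lengths 2 and 3)
diamond_dag <- function() {
  ontology_from_parents(list(
    root = character(0),
    X = c(root = "is_a"),
    Y = c(root = "is_a"),
    Z = c(Y = "is_a"),
    D = c(X = "is_a", Z = "is_a")
  ))
}

# random small DAG over n terms: term i > 1 gets 1-2 parents among earlier
# terms, random relations
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  parents <- list()
  parents[[ids[1L]]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    k <- sample(1:min(2L, i - 1L), 1L)
    ps <- sample(ids[seq_len(i - 1L)], k)
    rel <- sample(c("is_a", "part_of"), k, replace = TRUE)
    parents[[ids[i]]] <- stats::setNames(rel, ps)
  }
  ontology_from_parents(parents)
}

edge_frame_for_tests <- function(source, target, layer, weight, directed) {
  dynafic:::edge_frame(source, target, layer,
                       rep_len(weight, length(source)), directed)
}

# --- independent oracles -------------------------------------------------

# Wang S-values by exhaustive upward path enumeration: S_term(t) is the
# max over all directed paths term -> t of the product of contribution
# factors (independent of the package's relaxation algorithm).
oracle_svalues <- function(term, dag, contrib = c(is_a = 0.8, part_of = 0.6)) {
  best <- new.env()
  assign(term, 1, envir = best)
  walk <- function(node, value) {
    rels <- dag$parents[[node]]
    for (i in seq_along(rels)) {
      p <- names(rels)[i]
      v <- value * contrib[[rels[[i]]]]
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (v > cur) assign(p, v, envir = best)
      walk(p, v)
    }
  }
  walk(term, 1)
  vals <- mget(ls(best), envir = best)
  stats::setNames(as.numeric(vals), names(vals))
}

oracle_wang <- function(a, b, dag, contrib = c(is_a = 0.8, part_of = 0.6)) {
  sa <- oracle_svalues(a, dag, contrib)
  sb <- oracle_svalues(b, dag, contrib)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

# longest path to a root by exhaustive path enumeration
oracle_depth <- function(term, dag) {
  rels <- dag$parents[[term]]
  if (!length(rels)) return(0)
  1 + max(vapply(names(rels), oracle_depth, 0, dag = dag))
}

# 1-D optimal transport by the north-west-corner rule on sorted samples
# (exact for the |x - y| cost); independent of the cdf-integral route.
oracle_transport <- function(a, b) {
  a <- sort(a); b <- sort(b)
  ma <- rep(1 / length(a), length(a))
  mb <- rep(1 / length(b), length(b))
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(a) && j <= length(b)) {
    flow <- min(ma[i], mb[j])
    cost <- cost + flow * abs(a[i] - b[j])
    ma[i] <- ma[i] - flow
    mb[j] <- mb[j] - flow
    if (ma[i] <= 1e-15) i <- i + 1L
    if (j <= length(b) && mb[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# equal-size exact matching by permutation enumeration (n <= 4)
oracle_matching <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 4L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  min(vapply(perms(seq_along(b))
             , function(p) mean(abs(a - b[p])), 0))
}

# quick full-pipeline run over a generated bundle
run_bundle <- function(bundle, config = dynafic_config(permutations = 99),
                       out_dir = tempfile("out")) {
  suppressWarnings(suppressMessages(
    run_score(de = bundle$paths[["de"]], ppi = bundle$paths[["ppi"]],
              tf = bundle$paths[["tf"]], obo = bundle$paths[["obo"]],
              annotations = bundle$paths[["annotations"]],
              expression = bundle$paths[["expression"]],
              cancer_terms = bundle$paths[["cancer_terms"]],
              config = config, out_dir = out_dir)
  ))
}
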