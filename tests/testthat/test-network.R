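test_that("Wang similarity matches exhaustive path enumeration", {
  dag <- toy_dag()
  expect_equal(wang_term_similarity("B", "B", dag), 1.0)
  # value frozen from the exhaustive S-value table on the 4-term DAG:
  # S_B = {B:1, A:0.8, root:0.64}, S_C = {C:1, root:0.8}
  # shared = {root}; sim = (0.64 + 0.8) / (2.44 + 1.8)
  expect_equal(wang_term_similarity("B", "C", dag), 1.44 / 4.24)
  expect_equal(oracle_wang("B", "C", dag), 1.44 / 4.24)

  # no shared ancestor across disjoint roots
  dis <- ontology_from_parents(list(R1 = character(0), R2 = character(0),
                                    L1 = c(R1 = "is_a"),
                                    L2 = c(R2 = "is_a")))
  expect_equal(wang_term_similarity("L1", "L2", dis), 0)

  # exhaustive oracle over random DAGs with <= 6 terms, all pairs
  for (seed in 1:10) {
    dag <- random_dag(sample(3:6, 1), seed = seed)
    M <- term_similarity_matrix(dag$terms, dag)
    for (a in dag$terms) {
      for (b in dag$terms) {
        expect_equal(M[a, b], oracle_wang(a, b, dag), tolerance = 1e-12)
        expect_equal(M[a, b], M[b, a])
        expect_gte(M[a, b], 0); expect_lte(M[a, b], 1)
      }
    }
  }
})

test_that("gene functional similarity uses best-match averaging", {
  dag <- toy_dag()
  ann <- list(g1 = c("A", "B"), g2 = c("A", "B"), g3 = "B", g4 = "C",
              g5 = c("A", "B", "C"))
  expect_equal(gene_functional_similarity("g1", "g2", ann, dag), 1.0)
  # singleton sets degenerate to the term similarity
  expect_equal(gene_functional_similarity("g3", "g4", ann, dag),
               wang_term_similarity("B", "C", dag))
  # 2x3 sets against the brute-force matrix computed from term pairs
  S <- outer(c("A", "B"), c("A", "B", "C"),
             Vectorize(function(x, y) oracle_wang(x, y, dag)))
  bma <- (mean(apply(S, 1, max)) + mean(apply(S, 2, max))) / 2
  expect_equal(gene_functional_similarity("g1", "g5", ann, dag), bma)
  # unannotated gene is flagged undefined
  expect_true(is.na(gene_functional_similarity("g1", "gX", ann, dag)))
})

test_that("GO layer keeps pairs strictly above the similarity threshold", {
  dag <- toy_dag()
  ann <- list(g1 = c("A", "B"), g2 = c("A", "B"), g3 = "C")
  layer <- build_go_layer(c("g1", "g2", "g3"), ann, dag)
  expect_true(any(layer$source == "g1" & layer$target == "g2" &
                    layer$weight == 1))
  # threshold 1.0 with strict > yields an empty layer
  expect_equal(nrow(build_go_layer(c("g1", "g2"), ann, dag,
                                   threshold = 1.0)), 0L)
  # brute-force all-pairs filter on 5 genes
  set.seed(9)
  dag5 <- random_dag(6, seed = 2)
  ann5 <- lapply(stats::setNames(1:5, paste0("x", 1:5)), function(i)
    sample(dag5$terms, sample(1:3, 1)))
  got <- build_go_layer(names(ann5), ann5, dag5, threshold = 0.3)
  M <- term_similarity_matrix(dag5$terms, dag5)
  want <- 0L
  for (i in 1:4) for (j in (i + 1):5) {
    s <- gene_functional_similarity(names(ann5)[i], names(ann5)[j],
                                    ann5, dag5, term_sim = M)
    if (!is.na(s) && s > 0.3) want <- want + 1L
  }
  expect_equal(nrow(got), want)
})

test_that("layer integration builds a row-stochastic combined matrix", {
  ppi <- edge_frame_for_tests("a", "b", "ppi", 0.5, FALSE)
  net <- integrate_layers(ppi = ppi)
  expect_equal(as.numeric(net$W["a", "b"]), 1)
  expect_equal(as.numeric(net$W["b", "a"]), 1)

  # ppi 0.5 and go 0.4 on the same pair: 1.0*0.5 + 0.5*0.4 = 0.7
  go <- edge_frame_for_tests("a", "b", "go", 0.4, FALSE)
  net2 <- integrate_layers(ppi = ppi, go = go)
  expect_equal(as.numeric(net2$A["a", "b"]), 0.7)
  expect_equal(as.numeric(net2$A["b", "a"]), 0.7)

  # dangling tf target keeps a self-loop row
  tf <- edge_frame_for_tests("TF1", "g1", "tf", 1.0, TRUE)
  net3 <- integrate_layers(tf = tf)
  expect_equal(as.numeric(net3$W["TF1", "g1"]), 1)
  expect_equal(as.numeric(net3$W["g1", "g1"]), 1)
  expect_equal(unname(net3$tf_outdeg[["TF1"]]), 1L)

  expect_error(integrate_layers(), "empty node set")

  # row sums are exactly 1 on a messy random mixture, and edge order
  # does not matter
  set.seed(21)
  mk <- function(n, layer, directed) {
    s <- sample(letters[1:10], n, TRUE); t <- sample(letters[1:10], n, TRUE)
    keep <- s != t
    edge_frame_for_tests(if (directed) s[keep] else pmin(s, t)[keep],
                         if (directed) t[keep] else pmax(s, t)[keep],
                         layer, runif(sum(keep)), directed)
  }
  ppiR <- mk(12, "ppi", FALSE); tfR <- mk(6, "tf", TRUE)
  goR <- mk(8, "go", FALSE)
  net4 <- integrate_layers(ppiR, tfR, goR, nodes = "zz")
  expect_true(all(abs(Matrix::rowSums(net4$W) - 1) < 1e-12))
  shuf <- function(e) e[sample(nrow(e)), , drop = FALSE]
  net5 <- integrate_layers(shuf(ppiR), shuf(tfR), shuf(goR), nodes = "zz")
  expect_equal(as.matrix(net5$W), as.matrix(net4$W))

  # removing go and tf reduces W to the normalized PPI adjacency
  net_ppi <- integrate_layers(ppi = ppiR, nodes = net4$nodes)
  refA <- net_ppi$A / pmax(Matrix::rowSums(net_ppi$A), 1e-300)
  expect_equal(as.matrix(net_ppi$W)[Matrix::rowSums(net_ppi$A) > 0, ],
               as.matrix(refA)[Matrix::rowSums(net_ppi$A) > 0, ])
})

test_that("degree centrality counts multi-layer pairs once", {
  # path graph a-b-c-d: centralities (1/3, 2/3, 2/3, 1/3)
  ppi <- edge_frame_for_tests(c("a", "b", "c"), c("b", "c", "d"),
                              "ppi", 0.9, FALSE)
  net <- integrate_layers(ppi = ppi)
  expect_equal(unname(degree_centrality(net)[c("a", "b", "c", "d")]),
               c(1, 2, 2, 1) / 3)
  # star center and isolated node
  star <- integrate_layers(
    ppi = edge_frame_for_tests(rep("hub", 4), paste0("x", 1:4), "ppi",
                               0.5, FALSE), nodes = "iso")
  cent <- degree_centrality(star)
  expect_equal(unname(cent[["hub"]]), 4 / 5)
  expect_equal(unname(cent[["iso"]]), 0)
  # tf direction ignored and duplicated pair counted once
  both <- integrate_layers(
    ppi = edge_frame_for_tests("a", "b", "ppi", 0.5, FALSE),
    tf = edge_frame_for_tests("a", "b", "tf", 1, TRUE))
  expect_equal(unname(degree_centrality(both)[["a"]]), 1)
  expect_error(degree_centrality(integrate_layers(nodes = "solo")),
               "at least two")
})

test_that("edge-metric correlations behave on constructed layers", {
  w <- c(0.2, 0.5, 0.9, 0.4)
  s <- letters[1:4]; t <- letters[5:8]
  identical_layers <- integrate_layers(
    ppi = edge_frame_for_tests(s, t, "ppi", w, FALSE),
    go = edge_frame_for_tests(s, t, "go", w, FALSE))
  r <- edge_metric_correlations(identical_layers)
  expect_equal(r$r["ppi", "go"], 1)
  anti <- integrate_layers(
    ppi = edge_frame_for_tests(s, t, "ppi", w, FALSE),
    go = edge_frame_for_tests(s, t, "go", 1 - w, FALSE))
  expect_equal(edge_metric_correlations(anti)$r["ppi", "go"], -1)

  # independent random weights decorrelate (n = 500 pairs)
  set.seed(123)
  n <- 500
  ss <- sprintf("p%03da", 1:n); tt <- sprintf("p%03db", 1:n)
  ind <- integrate_layers(
    ppi = edge_frame_for_tests(ss, tt, "ppi", runif(n), FALSE),
    go = edge_frame_for_tests(ss, tt, "go", runif(n), FALSE),
    tf = edge_frame_for_tests(ss, tt, "tf", runif(n), TRUE))
  rr <- edge_metric_correlations(ind)$r
  expect_lt(max(abs(rr[upper.tri(rr)])), 0.1)
  expect_error(edge_metric_correlations(integrate_layers(
    ppi = edge_frame_for_tests("a", "b", "ppi", 0.5, FALSE))),
    "at least 3")
})
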