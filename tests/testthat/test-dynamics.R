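test_that("volatility index normalizes CV and rewards centrality", {
  X <- rbind(flat = c(0.2, 0.2, 0.2),
             decay = c(1, 0.5, 0.25),
             steep = c(1, 0.1, 0.01))
  cent <- c(flat = 1, decay = 0, steep = 1)
  s <- svi(X, cent)
  expect_equal(unname(s[["flat"]]), 0)
  expect_equal(unname(s[["steep"]]), 1)  # max cv, centrality 1
  cv <- apply(X, 1, function(r) sd(r) / (mean(r) + 1e-12))
  expect_equal(unname(s[["decay"]]),
               0.5 * cv[["decay"]] / max(cv))
  expect_true(all(s >= 0 & s <= 1))
  # constant-zero trajectory scores 0
  s0 <- svi(rbind(z = c(0, 0, 0), d = c(1, 0.5, 0.2)), c(z = 1, d = 0))
  expect_equal(unname(s0[["z"]]), 0)
})

test_that("functional heterogeneity mixes entropy and neighborhood size", {
  # 10-node universe: gene "hub" with 4 neighbors of categories A,A,B,B;
  # hub itself category C; 3 categories in the universe
  ppi <- edge_frame_for_tests(rep("hub", 4), paste0("n", 1:4), "ppi",
                              0.8, FALSE)
  net <- integrate_layers(ppi = ppi, nodes = paste0("iso", 1:5))
  cats <- c(hub = "C", n1 = "A", n2 = "A", n3 = "B", n4 = "B",
            iso1 = "A", iso2 = "B", iso3 = "C", iso4 = "A", iso5 = "B")
  fh <- functional_heterogeneity(net, cats)
  p <- c(2, 2, 1) / 5
  H <- -sum(p * log(p))
  expect_equal(unname(fh[["hub"]]), (H / log(3)) * 4 / 10)
  expect_equal(unname(fh[["iso1"]]), 0)
  # all-one-category neighborhood has zero entropy
  same <- functional_heterogeneity(net, stats::setNames(
    rep("A", 10), names(cats)))
  expect_true(all(same == 0))
  expect_true(all(fh >= 0 & fh <= 1))
})

test_that("hierarchy disruption flags 2-sd outliers of the difference", {
  fh_l <- stats::setNames(rep(0.1, 5), paste0("g", 1:5))
  # identical distributions: zero distance, nothing disrupted
  hd0 <- hierarchy_disruption(fh_l, fh_l)
  expect_equal(hd0$wasserstein, 0)
  expect_length(hd0$disrupted, 0L)
  # d = (0,0,0,0,10): mean 2, sd 4.47 -> |10 - 2| < 2 sd, NOT flagged
  fh_r <- fh_l + c(0, 0, 0, 0, 10)
  hd <- hierarchy_disruption(fh_l, fh_r)
  expect_length(hd$disrupted, 0L)
  # a genuinely extreme point against a tight background is flagged
  # (needs enough background genes: with n = 5 no point can sit beyond
  # 2 sample standard deviations)
  fh_l10 <- stats::setNames(rep(0.1, 10), paste0("g", 1:10))
  fh_r2 <- fh_l10 + c(rnorm(9, 0, 0.002), 5)
  expect_equal(hierarchy_disruption(fh_l10, fh_r2)$disrupted, "g10")
  # translation property: shifting one side by c moves the distance by c
  expect_equal(hierarchy_disruption(fh_l, fh_l + 0.37)$wasserstein, 0.37)
  # zero spread yields an empty disrupted list
  expect_length(hierarchy_disruption(fh_l, fh_l + 1)$disrupted, 0L)
})

test_that("1-D Wasserstein agrees with independent transport oracles", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(c(0, 1), c(1, 2)), 1.0)
  set.seed(19)
  for (rep in 1:40) {
    a <- sample(-5:5, sample(1:5, 1), replace = TRUE)
    b <- sample(-5:5, sample(1:5, 1), replace = TRUE)
    expect_equal(wasserstein_1d(a, b), oracle_transport(a, b),
                 tolerance = 1e-12)
    if (length(a) == length(b) && length(a) <= 4) {
      expect_equal(wasserstein_1d(a, b), oracle_matching(a, b),
                   tolerance = 1e-12)
    }
  }
  # equal sizes reduce to the mean absolute sorted difference
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))))
})

test_that("permutation p-value is floored, valid and calibrated", {
  a <- c(1, 2, 3); b <- a
  pa <- wasserstein_permutation_p(a, b, B = 99, seed = 1)
  expect_equal(pa$statistic, 0)
  expect_equal(pa$p, 1)
  # permutation floor at 1 / (B + 1)
  far <- wasserstein_permutation_p(1:20, 101:120, B = 99, seed = 1)
  expect_equal(far$p, 1 / 100)
  # under the null the p-value is rarely small (calibration over seeds)
  ps <- vapply(1:30, function(s) {
    set.seed(s)
    wasserstein_permutation_p(rnorm(50), rnorm(50), B = 199,
                              seed = 1000 + s)$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("Welch test matches the textbook statistic", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(got$t, (mean(a) - mean(b)) / se)
  # scale invariance of the statistic
  expect_equal(welch_t(10 * a, 10 * b)$t, got$t)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("trajectory clustering recovers planted shapes and outliers", {
  make_planted <- function(seed, sigma = 0.04) {
    set.seed(seed)
    t <- 0:5
    X <- rbind(
      t(sapply(1:10, function(i) exp(-0.15 * t) * runif(1, 0.8, 1.2) +
                 rnorm(6, 0, sigma))),
      t(sapply(1:10, function(i) exp(-1.2 * t) * runif(1, 0.8, 1.2) +
                 rnorm(6, 0, sigma))))
    X[X < 0] <- 0
    rownames(X) <- sprintf("g%02d", 1:20)
    X
  }
  cl <- cluster_trajectories(make_planted(1), seed = 1)
  expect_equal(cl$k, 2L)
  expect_gt(cl$silhouette, 0.8)
  truth <- rep(1:2, each = 10)
  found <- as.integer(cl$labels)
  expect_true(all(table(truth, found) %in% c(0L, 10L)))
  # determinism given the seed
  cl2 <- cluster_trajectories(make_planted(1), seed = 1)
  expect_identical(cl$labels, cl2$labels)

  # a gene at 100x mass is flagged as an outlier
  X <- make_planted(2)
  X["g01", ] <- X["g01", ] * 100
  clo <- cluster_trajectories(X, seed = 2)
  expect_true("g01" %in% clo$outliers)
  expect_equal(unname(clo$labels[["g01"]]), "OUTLIER")
  expect_true(clo$outlier_assignment[["g01"]] %in%
                as.character(seq_len(clo$k)))

  # identical trajectories degenerate gracefully
  Xd <- matrix(rep(c(1, 0.5, 0.2), each = 6), nrow = 6,
               dimnames = list(paste0("g", 1:6), NULL))
  cld <- cluster_trajectories(Xd, seed = 1)
  expect_true(cld$degenerate)
  expect_equal(cld$k, 2L)
  expect_true(is.na(cld$silhouette))
})

test_that("planted two-cluster recovery survives 20% noise", {
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    t <- 0:5
    X <- rbind(
      t(sapply(1:10, function(i) exp(-0.15 * t) + rnorm(6, 0, 0.12))),
      t(sapply(1:10, function(i) exp(-1.3 * t) + rnorm(6, 0, 0.12))))
    X[X < 0] <- 0
    rownames(X) <- sprintf("g%02d", 1:20)
    cluster_trajectories(X, seed = seed)$k == 2L
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("correlation, enrichment and ablation statistics are exact", {
  de <- data.frame(gene = paste0("g", 1:5), log2fc = c(1, 2, 3, 4, 5))
  scores <- data.frame(gene = paste0("g", 1:5),
                       dynafic_scaled = 10 * c(1, 2, 3, 4, 5))
  expect_equal(expression_influence_correlation(de, scores), 1)
  scores$dynafic_scaled <- rev(scores$dynafic_scaled)
  expect_equal(expression_influence_correlation(de, scores), -1)
  expect_error(expression_influence_correlation(de[1:2, ], scores),
               "at least 3")

  # hypergeometric closed forms
  u <- paste0("u", 1:20)
  expect_equal(hypergeom_enrichment(u, u, u), 1)
  expect_equal(hypergeom_enrichment(u[1:5], u[1:5], u),
               1 / choose(20, 5))
  expect_gt(hypergeom_enrichment(u[1:5], u[6:7], u), 0.4)
  expect_error(hypergeom_enrichment("a", "a", character(0)), "empty")

  a <- stats::setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  expect_equal(ablation_compare(a, a), 1)
  expect_equal(ablation_compare(a, rev(setNames(a, names(a)))), 1)
  expect_equal(ablation_compare(a, stats::setNames(rev(unname(a)),
                                                   names(a))), -1)
})

test_that("set arithmetic reproduces the printed cohort worked example", {
  simple <- paste0("s", 1:277)
  adjusted <- c(simple[1:96], paste0("n", 1:9))
  st <- set_comparison_stats(simple, adjusted)
  expect_equal(st$lost_n, 181L)
  expect_equal(st$lost_pct, 100 * 181 / 277)  # prints as 65.3
  expect_equal(st$gained_n, 9L)
  expect_equal(st$shared_n, 96L)
  expect_equal(st$jaccard_pct, 100 * 96 / 286)  # prints as 33.6
  expect_equal(set_comparison_stats(c("a"), c("b"))$jaccard_pct, 0)
  same <- set_comparison_stats(letters, letters)
  expect_equal(same$lost_n, 0L)
  expect_equal(same$jaccard_pct, 100)
})

test_that("proportion comparisons match the printed percentages", {
  msi <- contingency_props(18, 369, 59, 219)
  expect_equal(msi$pct_a, 4.9)
  expect_equal(msi$pct_b, 26.9)
  expect_lt(msi$chi2_p, 1e-10)
  braf <- contingency_props(7, 304, 44, 208)
  expect_equal(braf$pct_a, 2.3)
  expect_equal(braf$pct_b, 21.2)
  eq <- contingency_props(10, 100, 10, 100)
  expect_equal(eq$chi2_p, 1)
  # Fisher variant available behind the flag
  expect_lt(contingency_props(18, 369, 59, 219, exact = TRUE)$chi2_p,
            1e-10)
  expect_error(contingency_props(1, 0, 1, 10), "b_n > 0|a_n > 0")
})
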