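as_ft <- function(m, prefix = "s") {
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  feature_table(m, stats::setNames(rep("A", ncol(m)), colnames(m)))
}

test_that("Spearman rho is exact on monotone pairs and matches the rank-Pearson oracle", {
  m <- rbind(x = c(1, 2, 3, 4, 5), y = c(2, 4, 6, 8, 10), z = c(10, 8, 6, 4, 2))
  co <- spearman_matrix(as_ft(m))
  p <- co$pairs
  expect_equal(p$rho[p$taxon_a == "x" & p$taxon_b == "y"], 1.0)
  expect_equal(p$rho[p$taxon_a == "x" & p$taxon_b == "z"], -1.0)

  # 50 random pairs with ties, checked against rank-then-Pearson to 1e-12
  set.seed(42)
  for (k in 1:50) {
    n <- sample(8:30, 1)
    a <- round(rgamma(n, 2, 1), 1)   # rounding forces ties
    b <- round(a * runif(1, -2, 2) + rnorm(n), 1)
    if (sd(a) == 0 || sd(b) == 0 || sd(rank(b)) == 0) next
    co <- spearman_matrix(rbind(a = a, b = b))   # matrix path: values may be negative
    expect_equal(co$pairs$rho, oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("rho is invariant under a shared permutation of samples", {
  ft <- random_table(8, 12, seed = 5)
  co1 <- spearman_matrix(ft)
  perm <- sample(ncol(ft$counts))
  ft2 <- feature_table(ft$counts[, perm], ft$groups[perm])
  co2 <- spearman_matrix(ft2)
  expect_equal(co1$pairs$rho, co2$pairs$rho, tolerance = 1e-12)
})

test_that("constant taxa go to the degenerate set and small n errors", {
  m <- rbind(a = c(1, 2, 3, 4, 5), flat = rep(3, 5), b = c(5, 1, 4, 2, 3))
  co <- spearman_matrix(as_ft(m))
  expect_equal(nrow(co$pairs) + nrow(co$degenerate), choose(3, 2))
  expect_true(all(co$degenerate$taxon_a == "flat" | co$degenerate$taxon_b == "flat"))
  expect_error(spearman_matrix(as_ft(m[, 1:3])), class = "cooccurnet_small_n")
})

test_that("exact permutation p-values match the tie-free exact distribution", {
  set.seed(7)
  for (n in c(5, 6, 7)) {
    for (k in 1:5) {
      x <- sample(n); y <- sample(n)
      got <- correlation_test(x, y, method = "exact")
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = TRUE))
      expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(got$p, min(1, ref$p.value), tolerance = 1e-10)
    }
  }
})

test_that("t-approximation rejects at close to nominal rate under the null", {
  set.seed(11)
  rej <- mean(replicate(2000, correlation_test(rnorm(30), rnorm(30))$p) < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(13)
  for (k in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "cooccurnet_bad_argument")
})

test_that("edge rule applies strict thresholds and matches a brute-force filter", {
  pairs <- data.frame(taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
                      rho = c(0.29, -0.80, 0.31), p = c(0.001, 0.001, 0.2),
                      q = c(0.001, 0.001, 0.2), stringsAsFactors = FALSE)
  corr <- structure(list(pairs = pairs, degenerate = pairs[0, 1:2],
                         taxa = c("a", "b", "c"), n = 8, p_method = "t_approx"),
                    class = "correlation_result")
  net <- build_network(corr, edge_rule())
  expect_equal(nrow(net$edges), 1L)       # 0.29 fails |rho|, 0.31 fails q
  expect_equal(net$edges$weight, 0.80)
  expect_equal(net$edges$sign, "negative")

  ft <- random_table(15, 10, seed = 21)
  co <- spearman_matrix(ft)
  rule <- edge_rule(rho_min = 0.4, q_max = 0.8)
  got <- build_network(co, rule)$edges
  want <- co$pairs[abs(co$pairs$rho) > 0.4 & co$pairs$q < 0.8, ]
  expect_equal(pair_key(got$taxon_a, got$taxon_b),
               pair_key(want$taxon_a, want$taxon_b))
})

test_that("descriptors handle empty and complete graphs and match an adjacency oracle", {
  empty <- structure(list(nodes = letters[1:5],
                          edges = data.frame(taxon_a = character(0),
                                             taxon_b = character(0),
                                             weight = numeric(0),
                                             sign = character(0))),
                     class = "cooccurrence_network")
  d <- describe_network(empty)
  expect_equal(d$n_edges, 0L)
  expect_equal(d$density, 0)
  expect_equal(d$n_components, 0L)

  tri <- structure(list(nodes = c("a", "b", "c"),
                        edges = data.frame(taxon_a = c("a", "a", "b"),
                                           taxon_b = c("b", "c", "c"),
                                           weight = 1, sign = "positive")),
                   class = "cooccurrence_network")
  dt <- describe_network(tri)
  expect_equal(dt$density, 1.0)
  expect_equal(dt$mean_degree, 2.0)
  expect_equal(dt$largest_component_size, 3L)

  set.seed(31)
  for (k in 1:10) {
    nodes <- sprintf("n%02d", 1:20)
    npairs <- t(combn(nodes, 2))
    pick <- runif(nrow(npairs)) < 0.08
    e <- npairs[pick, , drop = FALSE]
    signs <- sample(c("positive", "negative"), nrow(e), replace = TRUE)
    g <- structure(list(nodes = nodes,
                        edges = data.frame(taxon_a = e[, 1], taxon_b = e[, 2],
                                           weight = 0.5, sign = signs,
                                           stringsAsFactors = FALSE)),
                   class = "cooccurrence_network")
    got <- unclass(describe_network(g))
    ref <- oracle_descriptors(nodes, e[, 1], e[, 2], signs)
    for (nm in names(ref))
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12,
                   ignore_attr = TRUE, label = nm)
  }
})

test_that("sensitivity curve is monotone, hits zero at impossible cutoffs and recounts exactly", {
  ft <- random_table(15, 10, seed = 41)
  co <- spearman_matrix(ft)
  sc <- threshold_sensitivity(co, edge_rule(q_max = 0.9))
  expect_true(all(diff(sc$n_edges) <= 0))
  sc2 <- threshold_sensitivity(co, edge_rule(q_max = 0.9), thresholds = c(0.5, 1.0))
  expect_equal(sc2$n_edges[2], 0L)
  for (i in seq_len(nrow(sc))) {
    manual <- sum(abs(co$pairs$rho) > sc$threshold[i] & co$pairs$q < 0.9)
    expect_equal(sc$n_edges[i], manual)
  }
  expect_error(threshold_sensitivity(co, thresholds = c(0.5, 0.2)),
               class = "cooccurnet_bad_argument")
})
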