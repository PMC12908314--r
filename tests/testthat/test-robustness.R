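test_that("an identity replicate gives support 1 to exactly the observed edges", {
  d <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 12,
                                       blocks = list(list(taxa = 1:3, rho = 0.9)),
                                       seed = 3))
  n <- ncol(d$table$counts)
  br <- bootstrap_networks(d$table, B = 1, replicate_indices = list(seq_len(n)))
  obs <- br$network$edges
  es <- br$edge_support
  k_obs <- pair_key(obs$taxon_a, obs$taxon_b)
  k_all <- pair_key(es$taxon_a, es$taxon_b)
  expect_true(all(es$support[k_all %in% k_obs] == 1.0))
  expect_true(all(es$support[!k_all %in% k_obs] == 0.0))
})

test_that("bootstrap and permutation reports are bitwise reproducible under one seed", {
  d <- generate_dataset(synthetic_spec(n_per_group = 6, n_taxa = 10, seed = 8))
  b1 <- bootstrap_networks(d$table, B = 30, seed = 123)
  b2 <- bootstrap_networks(d$table, B = 30, seed = 123)
  expect_identical(b1, b2)
  p1 <- permutation_null(d$table, P = 20, seed = 321)
  p2 <- permutation_null(d$table, P = 20, seed = 321)
  expect_identical(p1, p2)
  b3 <- bootstrap_networks(d$table, B = 30, seed = 124)
  expect_false(identical(b1$edge_support$support, b3$edge_support$support))
})

test_that("a strongly co-occurring pair keeps high bootstrap support; null pairs do not", {
  sup <- vapply(1:10, function(i) {
    d <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 60,
                                         blocks = list(list(taxa = 1:2, rho = 0.95)),
                                         seed = 500 + i))
    br <- bootstrap_networks(d$table, B = 200, seed = 600 + i)
    es <- br$edge_support
    es$support[es$taxon_a == "Taxon_01" & es$taxon_b == "Taxon_02"]
  }, numeric(1))
  expect_gte(mean(sup), 0.90)

  med <- vapply(1:10, function(i) {
    d <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 10,
                                         seed = 700 + i))
    median(bootstrap_networks(d$table, B = 200, seed = 800 + i)$edge_support$support)
  }, numeric(1))
  expect_true(all(med <= 0.10))
})

test_that("consensus thresholding is inclusive at the cutoff and scans the support map", {
  es <- data.frame(taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
                   support = c(0.70, 0.695, 0.9),
                   positive_fraction = c(1, 1, 0.2), stringsAsFactors = FALSE)
  report <- structure(list(edge_support = es,
                           hub_frequency = c(a = 1, b = 1, c = 0),
                           network = structure(list(nodes = c("a", "b", "c"),
                                                    edges = es[0, ],
                                                    rule = edge_rule()),
                                               class = "cooccurrence_network"),
                           B = 200L, k_hub = 3L, seed = 1L,
                           consensus_support_min = 0.70),
                      class = "bootstrap_report")
  cn <- consensus_network(report)
  got <- pair_key(cn$edges$taxon_a, cn$edges$taxon_b)
  expect_setequal(got, pair_key(c("a", "b"), c("b", "c")))
  expect_false(pair_key("a", "c") %in% got)
  expect_equal(cn$edges$sign[cn$edges$taxon_a == "b"], "negative")
  # brute-force scan of the support map
  expect_setequal(got, pair_key(es$taxon_a, es$taxon_b)[es$support >= 0.70])
})

test_that("hub frequencies lie in [0,1] and favour planted block members", {
  d <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 20,
                                       blocks = list(list(taxa = 1:5, rho = 0.9)),
                                       seed = 17))
  br <- bootstrap_networks(d$table, B = 100, seed = 18)
  expect_true(all(br$hub_frequency >= 0 & br$hub_frequency <= 1))
  block <- paste0("Taxon_", formatC(1:5, width = 2, flag = "0"))
  expect_gt(mean(br$hub_frequency[block]),
            mean(br$hub_frequency[setdiff(names(br$hub_frequency), block)]))
})

test_that("permutation replicates preserve each taxon's marginal multiset exactly", {
  d <- generate_dataset(synthetic_spec(n_per_group = 6, n_taxa = 12, seed = 29))
  pr <- permutation_null(d$table, P = 10, seed = 30, return_tables = TRUE)
  for (perm in pr$permuted_counts) {
    expect_false(identical(perm, d$table$counts) && pr$P > 1)  # shuffling happened
    for (i in seq_len(nrow(perm)))
      expect_identical(sort(perm[i, ]), sort(d$table$counts[i, ]),
                       ignore_attr = TRUE)
  }
})

test_that("empirical p uses the add-one estimator and detects planted structure", {
  d <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 30,
                                       blocks = list(list(taxa = 1:5, rho = 0.9)),
                                       seed = 31))
  pr <- permutation_null(d$table, P = 50, seed = 32)
  expect_equal(pr$empirical_p,
               (1 + sum(pr$null_edge_counts >= pr$observed_edges)) / (1 + pr$P))
  expect_gt(pr$observed_edges, max(pr$null_edge_counts))
  expect_equal(pr$empirical_p, 1 / 51)

  hits <- vapply(1:50, function(i) {
    di <- generate_dataset(synthetic_spec(n_per_group = 10, n_taxa = 30,
                                          blocks = list(list(taxa = 1:5, rho = 0.9)),
                                          seed = 60000 + i))
    permutation_null(di$table, P = 50, seed = 70000 + i)$empirical_p
  }, numeric(1))
  expect_gte(mean(hits <= 0.05), 0.90)
})

test_that("under global independence the observed rank within the null is uniform", {
  set.seed(99)
  u <- vapply(1:200, function(i) {
    d <- generate_dataset(synthetic_spec(n_per_group = 6, n_taxa = 15,
                                         seed = 1200 + i))
    pr <- permutation_null(d$table, P = 30, seed = 1300 + i)
    lt <- sum(pr$null_edge_counts < pr$observed_edges)
    eq <- sum(pr$null_edge_counts == pr$observed_edges)
    (lt + runif(1) * (eq + 1)) / (pr$P + 1)   # randomized tie-broken rank
  }, numeric(1))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("consensus recovery of a planted block grows with sample size beyond the tiny-n regime", {
  rec <- vapply(c(10, 20, 40), function(npg) {
    mean(vapply(1:20, function(i) {
      d <- generate_dataset(synthetic_spec(n_per_group = npg, n_taxa = 20,
                                           blocks = list(list(taxa = 1:5, rho = 0.8)),
                                           seed = 80000 + 1000 * npg + i))
      g <- subset_by_group(d$table, "NCD")
      cn <- consensus_network(bootstrap_networks(g, B = 200, seed = 90000 + i))
      true <- pair_key(d$truth$true_edges$taxon_a, d$truth$true_edges$taxon_b)
      got <- pair_key(cn$edges$taxon_a, cn$edges$taxon_b)
      mean(true %in% got)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_gt(rec[3], 0.8)
})
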