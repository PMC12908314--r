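# Independent oracles and fixture builders. Oracles deliberately take a
# different computational route from the package code they check.

# Step-up BH by the definition: sort ascending, q(i) = min over j >= i of
# p(j) * m / j capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho by rank-transform-then-Pearson through stats::cor.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (rank-sum deviation statistic); mirrors the definition, used on tie-free
# cases where wilcox.test's exact distribution is also available.
oracle_mw_exact <- function(x, y) {
  stats::wilcox.test(x, y, exact = TRUE)$p.value
}

# Network descriptors recomputed from an adjacency matrix, with components
# found by breadth-first search (no igraph).
oracle_descriptors <- function(nodes, edges_a, edges_b, signs) {
  N <- length(nodes)
  A <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  for (k in seq_along(edges_a)) {
    A[edges_a[k], edges_b[k]] <- 1L
    A[edges_b[k], edges_a[k]] <- 1L
  }
  deg <- rowSums(A)
  conn <- which(deg >= 1)
  seen <- rep(FALSE, N)
  sizes <- integer(0)
  for (s in conn) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]; size <- size + 1L
      nb <- which(A[v, ] == 1L & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  E <- length(edges_a)
  list(n_nodes_total = N,
       n_nodes_connected = length(conn),
       n_edges = E,
       density = if (N >= 2) 2 * E / (N * (N - 1)) else 0,
       mean_degree = if (N >= 1) 2 * E / N else 0,
       n_components = length(sizes),
       largest_component_size = if (length(sizes)) max(sizes) else 0L,
       positive_edge_fraction = if (E) mean(signs == "positive") else NA_real_)
}

# Random valid feature table for property checks.
random_table <- function(n_taxa = 12, n_samples = 8, seed = 1,
                         groups = NULL, lambda = 20) {
  set.seed(seed)
  counts <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                   dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                   sprintf("s%02d", seq_len(n_samples))))
  if (is.null(groups))
    groups <- rep(c("A", "B"), length.out = n_samples)
  feature_table(counts, stats::setNames(groups, colnames(counts)))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
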