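# Robustness of inferred networks at small n: bootstrap edge support / hub
# stability / consensus edges, and a permutation null for connectivity.

# Edge indicator vector over canonical pairs for one count matrix.
# Returns the logical edge mask plus the rho vector (for sign bookkeeping).
.edge_mask <- function(counts, idx, rule, readjust_q = TRUE, q_ref = NULL) {
  st <- .pair_stats(counts, idx)
  ok <- !st$degenerate
  q <- rep(NA_real_, length(st$rho))
  if (readjust_q) {
    q[ok] <- bh_adjust(st$p[ok])
  } else {
    q <- q_ref
  }
  edge <- ok & !is.na(q) & abs(st$rho) > rule$rho_min & q < rule$q_max
  list(edge = edge, rho = st$rho)
}

# Top-k nodes by degree with boundary ties all included; only nodes of
# degree >= 1 qualify as hubs.
.top_k_hubs <- function(deg, k) {
  pos <- which(deg > 0)
  if (!length(pos)) return(integer(0))
  v <- sort(deg[pos], decreasing = TRUE)
  thr <- v[min(k, length(v))]
  pos[deg[pos] >= thr]
}

#' Bootstrap edge support and hub stability
#'
#' Resamples the table's samples with replacement `B` times and rebuilds the
#' network on each replicate with the taxon set frozen from the input table
#' (no re-filtering, so edge identities are comparable across replicates).
#' For every canonical taxon pair the edge support is the fraction of
#' replicates in which the pair passes the edge rule; for every taxon the hub
#' frequency is the fraction of replicates in which it ranks among the top
#' `k_hub` nodes by degree (ties at the boundary all included; isolated nodes
#' never count as hubs). Replicate r uses a deterministic substream derived
#' from `(seed, r)`, so the report is reproducible and `B` can be extended
#' without disturbing earlier replicates.
#'
#' @param table A [feature_table()] with at least 4 samples, normally the
#'   filtered single-group table whose network is under study.
#' @param rule An [edge_rule()].
#' @param B Number of bootstrap replicates (default 200).
#' @param k_hub Number of top-degree slots defining a hub (default 3, the
#'   number of core genera typically reported per network).
#' @param seed Integer root seed.
#' @param readjust_q If `TRUE` (default) BH adjustment is re-run within each
#'   replicate; if `FALSE` the full-data q-values are reused and only rho is
#'   recomputed per replicate.
#' @param consensus_support_min Support cutoff stored for [consensus_network()]
#'   (default 0.70).
#' @param replicate_indices Optional list of `B` integer vectors overriding
#'   the resampled sample indices (for reproducing an exact resampling plan).
#' @return An object of class `bootstrap_report`: `edge_support` (data frame
#'   `taxon_a`, `taxon_b`, `support`, `positive_fraction` over all canonical
#'   pairs), `hub_frequency` (named numeric), the observed full-data
#'   `network`, and the parameters `B`, `k_hub`, `seed`,
#'   `consensus_support_min`.
#' @export
bootstrap_networks <- function(table, rule = edge_rule(), B = 200L, k_hub = 3L,
                               seed = 1L, readjust_q = TRUE,
                               consensus_support_min = 0.70,
                               replicate_indices = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(rule, "edge_rule"))
  counts <- table$counts
  n <- ncol(counts); m <- nrow(counts)
  if (n < 4L) abort("cooccurnet_small_n", "need at least 4 samples to bootstrap")
  if (B < 1L) abort("cooccurnet_bad_argument", "B must be >= 1")
  if (!is.null(replicate_indices) && length(replicate_indices) < B)
    abort("cooccurnet_bad_argument", "replicate_indices must supply one index vector per replicate")
  idx <- canonical_pairs(m)
  taxa <- rownames(counts)
  full_corr <- spearman_matrix(table)
  full_net <- build_network(full_corr, rule)
  q_ref <- rep(NA_real_, nrow(idx))
  if (!readjust_q) {
    ok_full <- !.pair_stats(counts, idx)$degenerate
    q_ref[ok_full] <- full_corr$pairs$q
  }
  support_count <- numeric(nrow(idx))
  pos_count <- numeric(nrow(idx))
  hub_count <- numeric(m)
  for (r in seq_len(B)) {
    if (is.null(replicate_indices)) {
      set.seed(substream_seed(seed, r))
      s <- sample.int(n, n, replace = TRUE)
    } else {
      s <- replicate_indices[[r]]
    }
    em <- .edge_mask(counts[, s, drop = FALSE], idx, rule,
                     readjust_q = readjust_q, q_ref = q_ref)
    support_count <- support_count + em$edge
    pos_count <- pos_count + (em$edge & em$rho > 0)
    deg <- tabulate(idx[em$edge, 1L], m) + tabulate(idx[em$edge, 2L], m)
    hubs <- .top_k_hubs(deg, k_hub)
    hub_count[hubs] <- hub_count[hubs] + 1
  }
  edge_support <- data.frame(
    taxon_a = taxa[idx[, 1L]], taxon_b = taxa[idx[, 2L]],
    support = support_count / B,
    positive_fraction = ifelse(support_count > 0, pos_count / support_count, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(edge_support = edge_support,
                 hub_frequency = stats::setNames(hub_count / B, taxa),
                 network = full_net,
                 B = as.integer(B), k_hub = as.integer(k_hub),
                 seed = as.integer(seed),
                 consensus_support_min = consensus_support_min,
                 readjust_q = readjust_q),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("<bootstrap_report> B = ", x$B, ", k_hub = ", x$k_hub,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  pairs with support >= ", x$consensus_support_min, ": ",
      sum(x$edge_support$support >= x$consensus_support_min), "\n", sep = "")
  hf <- sort(x$hub_frequency, decreasing = TRUE)
  hf <- hf[hf > 0]
  if (length(hf)) {
    show <- utils::head(hf, 5L)
    cat("  top hub frequencies: ",
        paste(names(show), format(show, digits = 2), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Consensus network from bootstrap edge support
#'
#' Keeps the pairs whose bootstrap support reaches the cutoff (inclusive:
#' support exactly at the cutoff is kept). Edge weight is the support
#' fraction; the sign is the majority sign across the replicates that
#' supported the edge (an exact tie is labelled positive).
#'
#' @param report A `bootstrap_report`.
#' @param support_min Support cutoff in `[0, 1]`; defaults to the value
#'   stored in the report (0.70 unless overridden).
#' @return A `cooccurrence_network` whose edge data frame carries `support`
#'   as the weight.
#' @export
consensus_network <- function(report, support_min = report$consensus_support_min) {
  stopifnot(inherits(report, "bootstrap_report"))
  es <- report$edge_support
  keep <- es$support >= support_min
  e <- es[keep, , drop = FALSE]
  edges <- data.frame(taxon_a = e$taxon_a, taxon_b = e$taxon_b,
                      weight = e$support,
                      sign = ifelse(!is.na(e$positive_fraction) & e$positive_fraction < 0.5,
                                    "negative", "positive"),
                      support = e$support,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = names(report$hub_frequency), edges = edges,
                 rule = report$network$rule, support_min = support_min),
            class = "cooccurrence_network")
}

#' Permutation null for network connectivity
#'
#' Destroys all cross-taxon association while preserving every taxon's
#' marginal distribution exactly: each replicate independently permutes, for
#' every taxon row separately, the order of its values across samples, then
#' rebuilds the network and records the edge count. The empirical p-value for
#' the observed connectivity uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + P)`, which is unbiased under
#' exchangeability and never returns zero.
#'
#' @param table A [feature_table()] with at least 4 samples.
#' @param rule An [edge_rule()].
#' @param P Number of permutation replicates (default 50).
#' @param seed Integer root seed; replicate r uses a substream derived from
#'   `(seed, r)`.
#' @param return_tables If `TRUE`, also return the permuted count matrices
#'   (used to verify that per-taxon marginals are preserved).
#' @return An object of class `permutation_report`: `null_edge_counts`
#'   (length `P`), `observed_edges`, `empirical_p`, `P`, `seed`, and
#'   optionally `permuted_counts`.
#' @export
permutation_null <- function(table, rule = edge_rule(), P = 50L, seed = 1L,
                             return_tables = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(rule, "edge_rule"))
  counts <- table$counts
  n <- ncol(counts); m <- nrow(counts)
  if (n < 4L) abort("cooccurnet_small_n", "need at least 4 samples")
  if (P < 1L) abort("cooccurnet_bad_argument", "P must be >= 1")
  idx <- canonical_pairs(m)
  observed <- sum(.edge_mask(counts, idx, rule)$edge)
  null_counts <- integer(P)
  kept <- if (return_tables) vector("list", P) else NULL
  for (r in seq_len(P)) {
    set.seed(substream_seed(seed, r))
    perm <- counts
    for (i in seq_len(m)) perm[i, ] <- counts[i, sample.int(n)]
    null_counts[r] <- sum(.edge_mask(perm, idx, rule)$edge)
    if (return_tables) kept[[r]] <- perm
  }
  structure(list(null_edge_counts = null_counts,
                 observed_edges = observed,
                 empirical_p = (1 + sum(null_counts >= observed)) / (1 + P),
                 P = as.integer(P), seed = as.integer(seed),
                 permuted_counts = kept),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("<permutation_report> P = ", x$P, ", observed edges = ", x$observed_edges,
      ", empirical p = ", format(x$empirical_p, digits = 3), "\n", sep = "")
  cat("  null edge counts: median ", stats::median(x$null_edge_counts),
      ", max ", max(x$null_edge_counts), "\n", sep = "")
  invisible(x)
}
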