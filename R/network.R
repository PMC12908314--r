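# All-pairs Spearman correlation, edge rule, graph construction and
# descriptors. This is the inference core: everything downstream (bootstrap,
# permutation null) re-runs these pieces.

# Rank rows with average ranks for ties; returns centered, unit-norm rank
# vectors plus a mask of constant (zero rank variance) taxa.
.rank_normalize <- function(counts) {
  R <- t(apply(counts, 1L, rank))
  ctr <- R - rowMeans(R)
  ss <- sqrt(rowSums(ctr * ctr))
  const <- ss == 0
  Z <- ctr / ifelse(const, 1, ss)
  list(Z = Z, const = const)
}

# Two-sided p for Spearman rho via the t approximation on n - 2 df.
.spearman_p_t <- function(rho, n) {
  denom <- 1 - rho * rho
  p <- ifelse(denom <= 0, 0,
              2 * pt(abs(rho) * sqrt((n - 2) / pmax(denom, .Machine$double.eps)),
                     df = n - 2, lower.tail = FALSE))
  pmin(p, 1)
}

# Exact two-sided permutation p for one pair (n <= 9). Enumerates all n!
# orderings of y's ranks; with ties present the enumeration is still a valid
# permutation test on midranks. Returns rho as well.
.spearman_exact_one <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  zx <- rx - mean(rx); sx <- sqrt(sum(zx * zx))
  zy <- ry - mean(ry); sy <- sqrt(sum(zy * zy))
  if (sx == 0 || sy == 0)
    abort("cooccurnet_constant_input", "constant input: Spearman correlation undefined")
  zx <- zx / sx; zy <- zy / sy
  rho <- min(1, max(-1, sum(zx * zy)))
  if (1 - abs(rho) < 1e-12) rho <- sign(rho)
  perms <- all_permutations(n)
  rho_all <- as.vector(matrix(zy[perms], nrow(perms), n) %*% zx)
  p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  c(rho = rho, p = p)
}

# Core pair statistics on a raw count matrix: canonical pairs, rho, p (t
# approximation), degenerate mask. Shared by spearman_matrix and the
# resampling loops, which must not pay object-construction overhead.
.pair_stats <- function(counts, idx = NULL) {
  n <- ncol(counts)
  rn <- .rank_normalize(counts)
  if (is.null(idx)) idx <- canonical_pairs(nrow(counts))
  a <- idx[, 1L]; b <- idx[, 2L]
  rho_mat <- tcrossprod(rn$Z)
  rho <- pmin(1, pmax(-1, rho_mat[idx]))
  snap <- 1 - abs(rho) < 1e-12
  rho[snap] <- sign(rho[snap])
  degenerate <- rn$const[a] | rn$const[b]
  rho[degenerate] <- NA_real_
  p <- rep(NA_real_, length(rho))
  p[!degenerate] <- .spearman_p_t(rho[!degenerate], n)
  list(a = a, b = b, rho = rho, p = p, degenerate = degenerate, n = n)
}

#' All-pairs Spearman correlation of taxa
#'
#' Computes, for every unordered pair of taxa, the Spearman coefficient
#' (Pearson correlation of average-fractional ranks), a two-sided p-value and
#' a Benjamini-Hochberg adjusted q-value. Pairs involving a taxon that is
#' constant across samples have no defined rank correlation and are set aside
#' as `degenerate` rather than treated as errors: after heavy filtering at
#' very small n such taxa are routine.
#'
#' @param table A [feature_table()] (or a plain numeric matrix with taxa as
#'   named rows) with at least 2 taxa and at least 4 samples.
#' @param p_method `"t_approx"` (default): two-sided tail of
#'   `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#'   the convention of mainstream implementations. `"exact"`: full
#'   enumeration over all `n!` orderings, available for `n <= 9`.
#' @return An object of class `correlation_result` with elements `pairs`
#'   (data frame `taxon_a`, `taxon_b`, `rho`, `p`, `q` over non-degenerate
#'   pairs, canonical order), `degenerate` (data frame of excluded pairs),
#'   `taxa`, `n` and `p_method`. BH adjustment is applied across the
#'   non-degenerate pairs of this table only.
#' @export
spearman_matrix <- function(table, p_method = c("t_approx", "exact")) {
  p_method <- match.arg(p_method)
  counts <- if (inherits(table, "feature_table")) table$counts else table
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("cooccurnet_bad_argument", "need a feature_table or numeric matrix")
  if (ncol(counts) < 4L)
    abort("cooccurnet_small_n", "need at least 4 samples for correlation inference")
  if (nrow(counts) < 2L)
    abort("cooccurnet_bad_argument", "need at least 2 taxa")
  taxa <- rownames(counts) %||% paste0("taxon", seq_len(nrow(counts)))
  st <- .pair_stats(counts)
  if (p_method == "exact") {
    if (st$n > 9L)
      abort("cooccurnet_bad_argument", "exact p-values require n <= 9")
    for (k in which(!st$degenerate)) {
      ex <- .spearman_exact_one(counts[st$a[k], ], counts[st$b[k], ])
      st$rho[k] <- ex[["rho"]]
      st$p[k] <- ex[["p"]]
    }
  }
  ok <- !st$degenerate
  q <- rep(NA_real_, length(st$rho))
  q[ok] <- bh_adjust(st$p[ok])
  pairs <- data.frame(taxon_a = taxa[st$a], taxon_b = taxa[st$b],
                      rho = st$rho, p = st$p, q = q,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs[ok, , drop = FALSE],
                 degenerate = pairs[!ok, c("taxon_a", "taxon_b"), drop = FALSE],
                 taxa = taxa, n = st$n, p_method = p_method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", length(x$taxa), " taxa, n = ", x$n,
      ", ", nrow(x$pairs), " pairs (", nrow(x$degenerate), " degenerate)\n", sep = "")
  invisible(x)
}

#' Two-sided p-value for a Spearman coefficient via the t approximation
#'
#' Computes the two-sided tail of `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, the p-value convention used for all reported
#' rank correlations. Useful for recomputing a p-value from a published
#' coefficient and sample size.
#'
#' @param rho Spearman coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 4).
#' @return Two-sided p-value(s).
#' @examples
#' spearman_p_value(-0.38, 8)
#' @export
spearman_p_value <- function(rho, n) {
  if (any(abs(rho) > 1)) abort("cooccurnet_bad_argument", "|rho| must be <= 1")
  if (n < 4L) abort("cooccurnet_small_n", "need n >= 4")
  .spearman_p_t(rho, n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: sort p ascending, take
#' `q(i) = min over j >= i of p(j) * m / j` capped at 1, and map back to the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    abort("cooccurnet_bad_argument", "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Edge retention rule
#'
#' A taxon pair becomes an edge when `|rho| > rho_min` (strict) and
#' `q < q_max` (strict).
#'
#' @param rho_min Threshold on the absolute Spearman coefficient, default 0.30.
#' @param q_max Threshold on the BH q-value, default 0.05.
#' @return An object of class `edge_rule`.
#' @export
edge_rule <- function(rho_min = 0.30, q_max = 0.05) {
  if (!is.numeric(rho_min) || length(rho_min) != 1L || rho_min < 0 || rho_min > 1)
    abort("cooccurnet_bad_argument", "rho_min must lie in [0, 1]")
  if (!is.numeric(q_max) || length(q_max) != 1L || q_max <= 0 || q_max > 1)
    abort("cooccurnet_bad_argument", "q_max must lie in (0, 1]")
  structure(list(rho_min = rho_min, q_max = q_max), class = "edge_rule")
}

#' Build the co-occurrence network from correlation results
#'
#' Edges are exactly the non-degenerate pairs passing the [edge_rule()];
#' the graph is undirected and weighted, with weight `|rho|` and the sign of
#' the association kept separately as an annotation. Every input taxon is a
#' node, so taxa isolated by the rule remain visible in the descriptors.
#'
#' @param corr A `correlation_result` from [spearman_matrix()].
#' @param rule An [edge_rule()].
#' @return An object of class `cooccurrence_network` with elements `nodes`
#'   (all taxa) and `edges` (data frame `taxon_a`, `taxon_b`, `weight`,
#'   `sign`, `rho`, `q`).
#' @export
build_network <- function(corr, rule = edge_rule()) {
  stopifnot(inherits(corr, "correlation_result"), inherits(rule, "edge_rule"))
  keep <- abs(corr$pairs$rho) > rule$rho_min & corr$pairs$q < rule$q_max
  e <- corr$pairs[keep, , drop = FALSE]
  edges <- data.frame(taxon_a = e$taxon_a, taxon_b = e$taxon_b,
                      weight = abs(e$rho),
                      sign = ifelse(e$rho < 0, "negative", "positive"),
                      rho = e$rho, q = e$q,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = corr$taxa, edges = edges, rule = rule),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param g A `cooccurrence_network`.
#' @return An undirected [igraph::graph] with all taxa as vertices and
#'   `weight`/`sign` edge attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "cooccurrence_network"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Structural descriptors of a co-occurrence network
#'
#' Reports the scalar connectivity summaries: node and edge counts, density
#' `2E / (N (N - 1))` over all retained taxa N (isolated nodes are genuine
#' outcomes of the edge rule and stay in the denominator), mean degree
#' `2E / N`, the number and largest size of connected components among
#' degree >= 1 nodes, and the fraction of positive edges.
#'
#' @param g A `cooccurrence_network`.
#' @return An object of class `network_descriptors` (a named list).
#' @export
describe_network <- function(g) {
  stopifnot(inherits(g, "cooccurrence_network"))
  N <- length(g$nodes)
  E <- nrow(g$edges)
  if (E > 0L) {
    ig <- as_igraph(g)
    deg <- igraph::degree(ig)
    comp <- igraph::components(ig)
    sizes <- comp$csize[comp$csize >= 2L]
    n_conn <- sum(deg >= 1L)
    n_comp <- length(sizes)
    largest <- max(sizes)
    pos_frac <- mean(g$edges$sign == "positive")
  } else {
    n_conn <- 0L; n_comp <- 0L; largest <- 0L; pos_frac <- NA_real_
  }
  structure(list(
    n_nodes_total = N,
    n_nodes_connected = n_conn,
    n_edges = E,
    density = if (N >= 2L) 2 * E / (N * (N - 1)) else 0,
    mean_degree = if (N >= 1L) 2 * E / N else 0,
    n_components = n_comp,
    largest_component_size = largest,
    positive_edge_fraction = pos_frac
  ), class = "network_descriptors")
}

#' @export
print.network_descriptors <- function(x, ...) {
  cat("<network_descriptors>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
as.data.frame.network_descriptors <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Sensitivity of network descriptors to the correlation cutoff
#'
#' Rebuilds the network over an ascending grid of `|rho|` cutoffs (the
#' q-value threshold is held fixed) and reports the descriptors at each, to
#' show how strongly conclusions depend on the chosen cutoff. The default
#' grid spans 0.15 to 0.50 in steps of 0.05.
#'
#' @param corr A `correlation_result`.
#' @param rule An [edge_rule()]; only its `q_max` is used.
#' @param thresholds Ascending numeric vector of cutoffs in `[0, 1]`.
#' @return An object of class `sensitivity_curve`: a data frame with a
#'   `threshold` column followed by the descriptor columns.
#' @export
threshold_sensitivity <- function(corr, rule = edge_rule(),
                                  thresholds = seq(0.15, 0.50, by = 0.05)) {
  stopifnot(inherits(corr, "correlation_result"))
  if (any(!is.finite(thresholds)) || any(thresholds < 0) || any(thresholds > 1))
    abort("cooccurnet_bad_argument", "thresholds must lie in [0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("cooccurnet_bad_argument", "thresholds must be strictly ascending")
  rows <- lapply(thresholds, function(t) {
    d <- describe_network(build_network(corr, edge_rule(rho_min = t, q_max = rule$q_max)))
    cbind(data.frame(threshold = t), as.data.frame(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}
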