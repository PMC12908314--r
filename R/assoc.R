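# Two-group screening and the taxa x metabolite / metabolite x cytokine
# Spearman association layer (fold changes, rank tests, star-annotated
# correlation matrices).

#' Construct a sample-by-feature measurement table
#'
#' Container for per-sample continuous measurements such as GC-MS short-chain
#' fatty acid concentrations or ELISA cytokine levels.
#'
#' @param values Numeric matrix, samples as rows (named), features as columns
#'   (named); finite, non-negative concentrations.
#' @param groups Named character vector mapping each sample id to its group,
#'   or a data frame with columns `sample_id` and `group`.
#' @return An object of class `sample_feature_table`.
#' @export
sample_feature_table <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("cooccurnet_malformed_input", "values must be a numeric matrix")
  if (is.null(rownames(values)) || (ncol(values) > 0L && is.null(colnames(values))))
    abort("cooccurnet_malformed_input", "values must have sample row names and feature column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    abort("cooccurnet_duplicate_ids", "duplicate sample or feature ids")
  if (any(!is.finite(values)))
    abort("cooccurnet_malformed_input", "values must be finite")
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), as.character(groups$sample_id))
  missing <- setdiff(rownames(values), names(groups))
  if (length(missing))
    abort("cooccurnet_metadata_mismatch",
          paste0("samples missing from metadata: ", paste(missing, collapse = ", ")))
  structure(list(values = values, groups = groups[rownames(values)]),
            class = "sample_feature_table")
}

#' @export
print.sample_feature_table <- function(x, ...) {
  cat("<sample_feature_table> ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Read a sample-by-feature table from TSV
#'
#' @param values_path TSV with sample ids in the first column and one column
#'   per feature.
#' @param metadata_path TSV with columns `sample_id` and `group`.
#' @return A [sample_feature_table()].
#' @export
read_sample_features <- function(values_path, metadata_path) {
  raw <- tryCatch(
    read.delim(values_path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) abort("cooccurnet_malformed_tsv", conditionMessage(e)))
  if (ncol(raw) < 2L)
    abort("cooccurnet_malformed_tsv", "values file needs a sample id column plus feature columns")
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    abort("cooccurnet_malformed_tsv", "non-numeric cells in values file")
  rownames(vals) <- as.character(raw[[1L]])
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    abort("cooccurnet_malformed_tsv", "metadata must have columns sample_id and group")
  sample_feature_table(vals, meta)
}

# Exact two-sided rank-sum p by full enumeration of the C(nA+nB, nA) group
# assignments of the pooled midranks. Valid with ties; two-sided via the
# symmetric deviation of the group-A rank sum from its null mean.
.rank_sum_exact_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  centre <- nx * (n + 1) / 2
  picks <- combn(n, nx)
  sums <- colSums(matrix(r[picks], nrow = nx))
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-9)
}

#' Two-group rank test
#'
#' Mann-Whitney U: when the pooled size is at most 12 the two-sided p-value
#' is computed by exact enumeration over all group assignments of the pooled
#' midranks (valid with ties, and symmetric under group swap); for larger
#' samples the normal approximation with tie correction is used. The
#' Kruskal-Wallis option applies the chi-square approximation with the two
#' groups as levels.
#'
#' @param x,y Numeric observation vectors for the two groups (each >= 2).
#' @param method `"mann_whitney"` (default) or `"kruskal_wallis"`.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
two_group_test <- function(x, y, method = c("mann_whitney", "kruskal_wallis")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L)
    abort("cooccurnet_bad_argument", "each group needs at least 2 observations")
  if (any(!is.finite(c(x, y))))
    abort("cooccurnet_bad_argument", "observations must be finite")
  p <- if (method == "kruskal_wallis") {
    g <- factor(rep(c("a", "b"), c(length(x), length(y))))
    kruskal.test(c(x, y), g)$p.value
  } else if (length(x) + length(y) <= 12L) {
    .rank_sum_exact_p(x, y)
  } else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Fold-change screen of features between two groups
#'
#' For every feature, the fold change is the ratio of arithmetic group means,
#' `mean(treatment) / mean(control)`, labelled `Up` when strictly greater
#' than 1 and `Down` otherwise, with a two-group rank test p-value attached.
#' No significance cutoff is hard-coded; filter the returned table at
#' whatever alpha the analysis calls for. A feature whose control mean is
#' zero gets `NA` fold change and is flagged.
#'
#' @param features A [sample_feature_table()].
#' @param control,treatment Group labels; the control group is the
#'   denominator.
#' @param method Test passed to [two_group_test()].
#' @return Data frame (class `screen_result`) with columns `feature_id`,
#'   `fold_change`, `direction`, `p`, `zero_control`.
#' @export
fold_change_screen <- function(features, control, treatment,
                               method = c("mann_whitney", "kruskal_wallis")) {
  stopifnot(inherits(features, "sample_feature_table"))
  method <- match.arg(method)
  for (g in c(control, treatment))
    if (!g %in% features$groups)
      abort("cooccurnet_unknown_group", paste0("unknown group: ", g))
  a <- features$values[features$groups == control, , drop = FALSE]
  b <- features$values[features$groups == treatment, , drop = FALSE]
  out <- lapply(colnames(features$values), function(f) {
    mc <- mean(a[, f]); mt <- mean(b[, f])
    fc <- if (mc == 0) NA_real_ else mt / mc
    data.frame(feature_id = f,
               fold_change = fc,
               direction = if (is.na(fc)) NA_character_ else if (fc > 1) "Up" else "Down",
               p = two_group_test(a[, f], b[, f], method = method),
               zero_control = mc == 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Spearman correlation test for one pair of variables
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param method `"t_approx"` (default): two-sided tail of
#'   `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df. `"exact"`: full
#'   enumeration over all `n!` orderings (n <= 9).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
correlation_test <- function(x, y, method = c("t_approx", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y))
    abort("cooccurnet_bad_argument", "x and y must have equal length")
  n <- length(x)
  if (n < 4L) abort("cooccurnet_small_n", "need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0)
    abort("cooccurnet_constant_input", "constant input: Spearman correlation undefined")
  if (method == "exact") {
    if (n > 9L) abort("cooccurnet_bad_argument", "exact p-values require n <= 9")
    ex <- .spearman_exact_one(x, y)
    return(list(rho = unname(ex[["rho"]]), p = unname(ex[["p"]]), n = n, method = method))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- min(1, max(-1, stats::cov(rx, ry) / (sd(rx) * sd(ry))))
  if (1 - abs(rho) < 1e-12) rho <- sign(rho)
  list(rho = rho, p = .spearman_p_t(rho, n), n = n, method = method)
}

#' Taxa-by-feature Spearman association matrix
#'
#' Correlates every taxon (as relative abundance) with every metabolite or
#' cytokine over a shared, identically ordered sample set, then applies BH
#' adjustment across all cells of the matrix and annotates cells from the raw
#' p-value: `**` for p < 0.01, `*` for 0.01 <= p < 0.05, empty otherwise.
#' Cells with a constant taxon or feature are returned with `NA` statistics.
#'
#' @param taxa A [feature_table()] (converted internally to relative
#'   abundance) or a numeric taxa-by-samples matrix of abundances.
#' @param features A [sample_feature_table()] or samples-by-features matrix.
#' @param method p-value method passed to [correlation_test()].
#' @return Long-format data frame (class `assoc_matrix`) with columns
#'   `row_id` (taxon), `col_id` (feature), `rho`, `p`, `q`, `stars`.
#' @export
taxa_feature_correlation <- function(taxa, features, method = c("t_approx", "exact")) {
  method <- match.arg(method)
  ab <- if (inherits(taxa, "feature_table")) to_relative_abundance(taxa) else taxa
  fv <- if (inherits(features, "sample_feature_table")) features$values else features
  if (!identical(colnames(ab), rownames(fv)))
    abort("cooccurnet_metadata_mismatch",
          "taxa and features must share an identically ordered sample set")
  cells <- expand.grid(row_id = rownames(ab), col_id = colnames(fv),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_list <- mapply(function(r, c) {
    x <- ab[r, ]; y <- fv[, c]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- correlation_test(x, y, method = method)
    c(ct$rho, ct$p)
  }, cells$row_id, cells$col_id)
  cells$rho <- stats_list[1L, ]
  cells$p <- stats_list[2L, ]
  cells$q <- NA_real_
  ok <- !is.na(cells$p)
  cells$q[ok] <- bh_adjust(cells$p[ok])
  cells$stars <- stars_from_p(cells$p)
  class(cells) <- c("assoc_matrix", "data.frame")
  cells
}
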