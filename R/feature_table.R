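#' Construct a taxon-by-sample feature table
#'
#' The basic container for amplicon-style count data: a non-negative integer
#' matrix with taxa (OTUs/ASVs/genera) as rows and samples as columns, plus a
#' group label for every sample.
#'
#' @param counts Numeric matrix of non-negative integer counts with unique
#'   taxon row names and unique sample column names.
#' @param groups Named character vector mapping every sample id to its group
#'   label (e.g. `"NCD"`, `"NCD_Pro"`), or a data frame with columns
#'   `sample_id` and `group`.
#' @return An object of class `feature_table` with elements `counts` (the
#'   validated matrix) and `groups` (named character vector aligned with the
#'   columns of `counts`).
#' @examples
#' counts <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'                  dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' ft <- feature_table(counts, c(s1 = "A", s2 = "B"))
#' @export
feature_table <- function(counts, groups) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("cooccurnet_malformed_input", "counts must be a numeric matrix")
  taxa <- rownames(counts)
  samples <- colnames(counts)
  if (is.null(taxa) || is.null(samples))
    abort("cooccurnet_malformed_input", "counts must have taxon row names and sample column names")
  if (anyDuplicated(taxa))
    abort("cooccurnet_duplicate_ids", "duplicate taxon ids in counts")
  if (anyDuplicated(samples))
    abort("cooccurnet_duplicate_ids", "duplicate sample ids in counts")
  if (any(!is.finite(counts)))
    abort("cooccurnet_malformed_input", "counts contain non-finite values")
  if (any(counts < 0))
    abort("cooccurnet_negative_counts", "counts contain negative values")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("cooccurnet_noninteger_counts", "counts contain non-integer values")
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups)))
      abort("cooccurnet_malformed_input", "metadata must have columns sample_id and group")
    if (anyDuplicated(groups$sample_id))
      abort("cooccurnet_duplicate_ids", "duplicate sample ids in metadata")
    groups <- stats::setNames(as.character(groups$group), as.character(groups$sample_id))
  }
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    abort("cooccurnet_metadata_mismatch",
          paste0("samples missing from metadata: ", paste(missing, collapse = ", ")))
  groups <- groups[samples]
  if (any(is.na(groups) | !nzchar(groups)))
    abort("cooccurnet_metadata_mismatch", "every sample needs a non-empty group label")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  structure(list(counts = counts, groups = groups), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$counts), " taxa x ", ncol(x$counts), " samples\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a feature table from counts and metadata TSV files
#'
#' @param counts_path Path to a tab-separated file with taxon ids in the first
#'   column and one column per sample (sample ids in the header row).
#' @param metadata_path Path to a tab-separated file with columns `sample_id`
#'   and `group`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(counts_path, metadata_path) {
  raw <- tryCatch(
    read.delim(counts_path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) abort("cooccurnet_malformed_tsv", conditionMessage(e)))
  if (ncol(raw) < 2L)
    abort("cooccurnet_malformed_tsv", "counts file needs a taxon id column plus sample columns")
  taxa <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))))
    abort("cooccurnet_malformed_tsv", "non-numeric count cells in counts file")
  counts <- as.matrix(vals)
  rownames(counts) <- taxa
  meta <- tryCatch(
    read.delim(metadata_path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) abort("cooccurnet_malformed_tsv", conditionMessage(e)))
  if (!all(c("sample_id", "group") %in% names(meta)))
    abort("cooccurnet_malformed_tsv", "metadata must have columns sample_id and group")
  feature_table(counts, meta)
}

#' Write a feature table to counts and metadata TSV files
#'
#' Inverse of [read_feature_table()]: `read_feature_table()` on the written
#' files reproduces the table exactly.
#'
#' @param table A [feature_table()].
#' @param counts_path,metadata_path Output file paths.
#' @return Invisibly, `table`.
#' @export
write_feature_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = names(table$groups), group = unname(table$groups),
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Convert counts to within-sample relative abundances
#'
#' Each sample column is divided by its total count. Samples with zero depth
#' are returned as all-zero columns with a warning rather than dropped, so the
#' sample set (and hence n in any resampling) is preserved.
#'
#' @param table A [feature_table()].
#' @return Numeric matrix of fractions with the same dimnames as the counts;
#'   non-empty columns sum to 1.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  depth <- colSums(table$counts)
  zero <- depth == 0
  if (any(zero)) {
    warning("zero-depth sample(s): ", paste(colnames(table$counts)[zero], collapse = ", "))
    depth[zero] <- 1
  }
  sweep(table$counts, 2L, depth, "/")
}

#' Specify abundance and prevalence filtering thresholds
#'
#' Defaults follow common practice for sparse genus-level tables: a global
#' relative-abundance floor of 0.1% and presence in at least 10% of samples.
#'
#' @param filter_thres Minimum global relative abundance (taxon total count /
#'   grand total count), a fraction in `[0, 1)`. Default 0.001.
#' @param prevalence_thres Minimum fraction of samples in which the taxon has
#'   a strictly positive count, in `[0, 1]`. Default 0.10.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(filter_thres = 0.001, prevalence_thres = 0.10) {
  if (!is.numeric(filter_thres) || length(filter_thres) != 1L ||
      filter_thres < 0 || filter_thres >= 1)
    abort("cooccurnet_bad_argument", "filter_thres must be a fraction in [0, 1)")
  if (!is.numeric(prevalence_thres) || length(prevalence_thres) != 1L ||
      prevalence_thres < 0 || prevalence_thres > 1)
    abort("cooccurnet_bad_argument", "prevalence_thres must be a fraction in [0, 1]")
  structure(list(filter_thres = filter_thres, prevalence_thres = prevalence_thres),
            class = "filter_spec")
}

#' Filter taxa by global relative abundance and prevalence
#'
#' Retains exactly the taxa whose global relative abundance (taxon total /
#' grand total over the table passed in) is at least `filter_thres` AND whose
#' prevalence (fraction of samples with count > 0) is at least
#' `prevalence_thres`. Both conditions are applied in one conjunctive pass, so
#' the operation is order-independent and idempotent. The sample set is never
#' changed. Global abundance is computed on the table given, so when networks
#' are built per group the filter is per group; filter the pooled table first
#' if pooled thresholds are wanted.
#'
#' @param table A [feature_table()].
#' @param spec A [filter_spec()].
#' @return The filtered `feature_table`; retained count rows are identical to
#'   the input rows.
#' @export
filter_taxa <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "filter_spec"))
  grand <- sum(table$counts)
  glob <- if (grand > 0) rowSums(table$counts) / grand else rep(0, nrow(table$counts))
  prev <- rowMeans(table$counts > 0)
  keep <- glob >= spec$filter_thres & prev >= spec$prevalence_thres
  if (!any(keep))
    abort("cooccurnet_empty_result", "filtering removed all taxa")
  feature_table(table$counts[keep, , drop = FALSE], table$groups)
}

#' Restrict a feature table to the samples of one group
#'
#' Taxon rows are left untouched; filtering is a separate explicit step.
#'
#' @param table A [feature_table()].
#' @param group A group label present in the table's metadata.
#' @return A `feature_table` containing only that group's samples.
#' @export
subset_by_group <- function(table, group) {
  stopifnot(inherits(table, "feature_table"))
  if (!group %in% table$groups)
    abort("cooccurnet_unknown_group", paste0("unknown group: ", group))
  keep <- table$groups == group
  feature_table(table$counts[, keep, drop = FALSE], table$groups[keep])
}
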