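# Plain-text writers for downstream use: TSV edge lists and JSON reports.

#' Write a network's edge list as TSV
#'
#' Columns: `taxon_a`, `taxon_b`, `rho`, `abs_rho`, `sign`, `p`, `q` (rho/p/q
#' columns are filled with `NA` for consensus networks, whose weights are
#' bootstrap support fractions).
#'
#' @param g A `cooccurrence_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "cooccurrence_network"))
  e <- g$edges
  out <- data.frame(taxon_a = e$taxon_a, taxon_b = e$taxon_b,
                    rho = if ("rho" %in% names(e)) e$rho else NA_real_,
                    abs_rho = e$weight,
                    sign = e$sign,
                    p = NA_real_,
                    q = if ("q" %in% names(e)) e$q else NA_real_,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Serializes network descriptors, sensitivity curves, bootstrap reports or
#' permutation reports (class attributes stripped; data frames as row
#' records).
#'
#' @param x A `network_descriptors`, `sensitivity_curve`, `bootstrap_report`
#'   or `permutation_report` (any list/data frame works).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  strip <- function(v) {
    if (is.data.frame(v)) { class(v) <- "data.frame"; v }
    else if (is.list(v)) { v <- lapply(v, strip); class(v) <- NULL; v }
    else v
  }
  jsonlite::write_json(strip(x), path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
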