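# Logistic-normal-multinomial generator for compositional count tables with
# planted structure (correlation blocks, group-differential taxa,
# taxon-linked metabolite and cytokine variables). Every pipeline stage is
# testable against the returned ground truth without external data.

#' Specify a synthetic dataset
#'
#' Parameters of the logistic-normal-multinomial generator. Counts arise by
#' drawing a latent Gaussian log-abundance vector per sample (block-structured
#' correlation within declared blocks, independent elsewhere), softmax-ing it
#' to a composition, and sampling counts multinomially at the sample's depth.
#' Metabolites and cytokines are lognormal variables tied to a chosen taxon's
#' latent value at a target Spearman correlation via the Gaussian copula
#' relation (see [generate_dataset()]).
#'
#' @param n_per_group Samples per group (default 4, the scale of a small
#'   rodent study).
#' @param n_taxa Number of taxa (default 60, a genus-level table).
#' @param depth Sequencing depth per sample: a single integer (default
#'   20000, fixed so count-level correlations are not confounded by depth
#'   variation) or a length-2 range sampled uniformly per sample.
#' @param blocks List of `list(taxa = <integer indices>, rho = <latent
#'   correlation in (-1, 1)>)`; block index sets must be disjoint.
#' @param differential List of `list(taxon = <index>, fold_change = <positive
#'   ratio>)`; the treatment group's latent mean for that taxon is shifted by
#'   `log(fold_change)`.
#' @param metabolite_links,cytokine_links Lists of `list(feature = <id>,
#'   taxon = <index>, rho = <target Spearman in (-1, 1)>)`.
#' @param feature_fold_changes Named numeric vector of group fold changes
#'   applied multiplicatively to treatment-group metabolite/cytokine values.
#' @param metabolite_ids,cytokine_ids Feature id vectors; ids appearing in
#'   links are added automatically.
#' @param zero_inflation Extra independent dropout probability applied to
#'   counts, in `[0, 1)` (default 0).
#' @param latent_sd Standard deviation of the per-sample latent log-abundance
#'   fluctuation (default 1, a realistic genus-level log-scale spread).
#' @param base_log_sd Spread of the fixed per-taxon baseline log-abundances
#'   (default 1.5, giving an uneven composition spanning roughly three
#'   orders of magnitude).
#' @param group_labels Length-2 character vector, control first
#'   (default `c("NCD", "NCD_Pro")`).
#' @param taxon_ids Optional taxon names (default `Taxon_01`, ...).
#' @param seed Integer seed making the dataset fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 4L, n_taxa = 60L, depth = 20000L,
                           blocks = list(), differential = list(),
                           metabolite_links = list(), cytokine_links = list(),
                           feature_fold_changes = NULL,
                           metabolite_ids = NULL, cytokine_ids = NULL,
                           zero_inflation = 0, latent_sd = 1, base_log_sd = 1.5,
                           group_labels = c("NCD", "NCD_Pro"),
                           taxon_ids = NULL, seed = 1L) {
  if (n_per_group < 2L) abort("cooccurnet_bad_argument", "n_per_group must be >= 2")
  if (n_taxa < 2L) abort("cooccurnet_bad_argument", "n_taxa must be >= 2")
  if (any(depth < 1) || !length(depth) %in% c(1L, 2L))
    abort("cooccurnet_bad_argument", "depth must be a positive integer or range")
  if (zero_inflation < 0 || zero_inflation >= 1)
    abort("cooccurnet_bad_argument", "zero_inflation must lie in [0, 1)")
  if (length(group_labels) != 2L || anyDuplicated(group_labels))
    abort("cooccurnet_bad_argument", "group_labels must be two distinct labels")
  all_block <- unlist(lapply(blocks, `[[`, "taxa"))
  if (anyDuplicated(all_block))
    abort("cooccurnet_bad_argument", "block taxon sets must be disjoint")
  for (b in blocks) {
    if (length(b$taxa) < 2L || any(b$taxa < 1L | b$taxa > n_taxa))
      abort("cooccurnet_bad_argument", "each block needs >= 2 valid taxon indices")
    if (abs(b$rho) >= 1) abort("cooccurnet_bad_argument", "|block rho| must be < 1")
  }
  for (d in differential) {
    if (d$taxon < 1L || d$taxon > n_taxa)
      abort("cooccurnet_bad_argument", "differential taxon index out of range")
    if (d$fold_change <= 0) abort("cooccurnet_bad_argument", "fold_change must be positive")
  }
  for (l in c(metabolite_links, cytokine_links)) {
    if (l$taxon < 1L || l$taxon > n_taxa)
      abort("cooccurnet_bad_argument", "link taxon index out of range")
    if (abs(l$rho) >= 1) abort("cooccurnet_bad_argument", "|link rho| must be < 1")
  }
  metabolite_ids <- union(metabolite_ids %||% character(0),
                          vapply(metabolite_links, `[[`, "", "feature"))
  cytokine_ids <- union(cytokine_ids %||% character(0),
                        vapply(cytokine_links, `[[`, "", "feature"))
  structure(list(
    n_per_group = as.integer(n_per_group), n_taxa = as.integer(n_taxa),
    depth = as.integer(depth), blocks = blocks, differential = differential,
    metabolite_links = metabolite_links, cytokine_links = cytokine_links,
    feature_fold_changes = feature_fold_changes,
    metabolite_ids = metabolite_ids, cytokine_ids = cytokine_ids,
    zero_inflation = zero_inflation, latent_sd = latent_sd,
    base_log_sd = base_log_sd, group_labels = group_labels,
    taxon_ids = taxon_ids, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Convert a target Spearman correlation to the latent Pearson correlation
#'
#' For bivariate Gaussian latents the population Spearman and Pearson
#' coefficients are related by `rho_s = (6 / pi) * asin(rho_p / 2)`; the
#' generator plants links at `rho_p = 2 * sin(pi * rho_s / 6)` so that the
#' population rank correlation of the (monotone-transformed) observables
#' equals the target.
#'
#' @param rho_s Target Spearman correlation in `(-1, 1)`.
#' @return The latent Pearson correlation.
#' @export
pearson_from_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Lognormal feature values tied to latent taxon scores at target Spearman rho.
.make_features <- function(ids, links, Z, n, base_log, log_sd) {
  vals <- matrix(NA_real_, n, length(ids), dimnames = list(rownames(Z), ids))
  link_of <- stats::setNames(links, vapply(links, `[[`, "", "feature"))
  for (f in ids) {
    l <- link_of[[f]]
    latent <- if (is.null(l)) rnorm(n) else {
      rp <- pearson_from_spearman(l$rho)
      rp * Z[, l$taxon] + sqrt(1 - rp^2) * rnorm(n)
    }
    vals[, f] <- exp(base_log + log_sd * latent)
  }
  vals
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws the full bundle of study-shaped data: a taxon-by-sample count table
#' with grouped samples, metabolite and cytokine measurement tables, and the
#' planted structure against which recovery can be scored. Deterministic
#' given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements `table`
#'   ([feature_table()]), `metabolites`, `cytokines` (each a
#'   [sample_feature_table()], possibly with zero features), and `truth`
#'   (`true_edges` data frame over planted block pairs, `true_differential`,
#'   `true_links`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- 2L * spec$n_per_group
  m <- spec$n_taxa
  groups <- rep(spec$group_labels, each = spec$n_per_group)
  sample_ids <- paste0(groups, "_", rep(seq_len(spec$n_per_group), 2L))
  taxa <- spec$taxon_ids %||% paste0("Taxon_", formatC(seq_len(m), width = 2, flag = "0"))
  if (length(taxa) != m) abort("cooccurnet_bad_argument", "taxon_ids length must equal n_taxa")

  mu <- rnorm(m, 0, spec$base_log_sd)
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(sample_ids, taxa))
  for (b in spec$blocks) {
    k <- length(b$taxa)
    Sigma <- matrix(b$rho, k, k); diag(Sigma) <- 1
    Z[, b$taxa] <- Z[, b$taxa] %*% chol(Sigma)
  }
  treated <- groups == spec$group_labels[2L]
  shift <- numeric(m)
  for (d in spec$differential) shift[d$taxon] <- log(d$fold_change)
  L <- sweep(spec$latent_sd * Z, 2L, mu, "+")
  L[treated, ] <- sweep(L[treated, , drop = FALSE], 2L, shift, "+")
  comp <- exp(L)
  comp <- comp / rowSums(comp)

  depths <- if (length(spec$depth) == 2L)
    sample(spec$depth[1L]:spec$depth[2L], n, replace = TRUE) else rep(spec$depth, n)
  counts <- matrix(0, m, n, dimnames = list(taxa, sample_ids))
  for (s in seq_len(n)) counts[, s] <- rmultinom(1L, depths[s], comp[s, ])
  if (spec$zero_inflation > 0) {
    drop <- matrix(rbinom(m * n, 1L, spec$zero_inflation), m, n) == 1L
    counts[drop] <- 0
  }
  group_map <- stats::setNames(groups, sample_ids)
  table <- feature_table(counts, group_map)

  metab <- .make_features(spec$metabolite_ids, spec$metabolite_links, Z, n,
                          base_log = log(50), log_sd = 0.5)
  cytok <- .make_features(spec$cytokine_ids, spec$cytokine_links, Z, n,
                          base_log = log(20), log_sd = 0.4)
  if (!is.null(spec$feature_fold_changes)) {
    for (f in names(spec$feature_fold_changes)) {
      fc <- spec$feature_fold_changes[[f]]
      if (f %in% colnames(metab)) metab[treated, f] <- metab[treated, f] * fc
      if (f %in% colnames(cytok)) cytok[treated, f] <- cytok[treated, f] * fc
    }
  }

  block_pairs <- do.call(rbind, lapply(spec$blocks, function(b) {
    pr <- canonical_pairs(length(b$taxa))
    data.frame(taxon_a = taxa[b$taxa[pr[, 1L]]], taxon_b = taxa[b$taxa[pr[, 2L]]],
               rho_latent = b$rho, stringsAsFactors = FALSE)
  }))
  truth <- list(
    true_edges = block_pairs %||% data.frame(taxon_a = character(0),
                                             taxon_b = character(0),
                                             rho_latent = numeric(0)),
    true_differential = data.frame(
      taxon = taxa[vapply(spec$differential, function(d) as.numeric(d$taxon), 1)],
      fold_change = vapply(spec$differential, function(d) as.numeric(d$fold_change), 1),
      stringsAsFactors = FALSE),
    true_links = data.frame(
      feature = vapply(c(spec$metabolite_links, spec$cytokine_links), `[[`, "", "feature"),
      taxon = taxa[vapply(c(spec$metabolite_links, spec$cytokine_links),
                          function(l) as.numeric(l$taxon), 1)],
      rho_target = vapply(c(spec$metabolite_links, spec$cytokine_links), `[[`, 1, "rho"),
      type = rep(c("metabolite", "cytokine"),
                 c(length(spec$metabolite_links), length(spec$cytokine_links))),
      stringsAsFactors = FALSE))

  structure(list(
    table = table,
    metabolites = sample_feature_table(metab, group_map),
    cytokines = sample_feature_table(cytok, group_map),
    truth = truth, spec = spec
  ), class = "synthetic_dataset")
}

#' Study-shaped fixture dataset
#'
#' One-call preset emulating the design of a small two-arm rodent microbiome
#' study: 2 groups (NCD control, NCD_Pro probiotic) of 4 samples, a 60-genus
#' count table at depth 20000 with mild zero inflation, a co-occurring block
#' of five control-associated genera (latent rho 0.8), probiotic-enriched
#' and -depleted differential genera, a nine-metabolite SCFA panel (acetic
#' through heptanoic acid) in which butyrate (BA) and caproate (CA) drop and
#' isocaproate (4-MVA) rises in the treated group, a planted negative
#' Clostridium-4-MVA link at Spearman -0.7, and two cytokines (TNF-a, IL-6)
#' tied to the same taxon so that 4-MVA correlates positively with TNF-a and
#' negatively with IL-6.
#'
#' @param seed Integer seed.
#' @return A `synthetic_dataset` (see [generate_dataset()]).
#' @export
study_shaped_dataset <- function(seed = 1L) {
  genera <- c("Lactobacillus", "Bifidobacterium", "Bacteroides", "Blautia",
              "Klebsiella", "Anaerostipes", "Ruminococcus", "Clostridium",
              "Enterococcus", "Desulfovibrio")
  taxa <- c(genera, paste0("Genus_", formatC(11:60, width = 2, flag = "0")))
  clostridium <- match("Clostridium", taxa)
  block <- match(c("Anaerostipes", "Ruminococcus", "Blautia", "Clostridium",
                   "Enterococcus"), taxa)
  scfa <- c("AA", "PA", "IBA", "BA", "IVA", "VA", "4-MVA", "CA", "HA")
  spec <- synthetic_spec(
    n_per_group = 4L, n_taxa = 60L, depth = 20000L,
    blocks = list(list(taxa = block, rho = 0.8)),
    differential = list(
      list(taxon = match("Lactobacillus", taxa), fold_change = 4),
      list(taxon = match("Bifidobacterium", taxa), fold_change = 4),
      list(taxon = clostridium, fold_change = 0.25)),
    metabolite_links = list(list(feature = "4-MVA", taxon = clostridium, rho = -0.7)),
    cytokine_links = list(
      list(feature = "TNF-a", taxon = clostridium, rho = -0.6),
      list(feature = "IL-6", taxon = clostridium, rho = 0.35)),
    feature_fold_changes = c("BA" = 0.27596907590426234,
                             "CA" = 0.27596907590426234,
                             "4-MVA" = 15.4593194512612,
                             "TNF-a" = 0.5, "IL-6" = 0.5),
    metabolite_ids = scfa, cytokine_ids = c("TNF-a", "IL-6"),
    zero_inflation = 0.05, taxon_ids = taxa, seed = seed)
  generate_dataset(spec)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `counts.tsv`, `metadata.tsv`, `metabolites.tsv`, `cytokines.tsv`
#' and `truth.json` into a directory.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$table, file.path(dir, "counts.tsv"),
                      file.path(dir, "metadata.tsv"))
  for (part in c("metabolites", "cytokines")) {
    sft <- dataset[[part]]
    df <- data.frame(sample_id = rownames(sft$values), sft$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, file.path(dir, paste0(part, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Round-trip a synthetic spec through a JSON configuration file
#'
#' @param spec A [synthetic_spec()].
#' @param path JSON file path.
#' @return `write_synthetic_spec()` invisibly returns `path`;
#'   `read_synthetic_spec()` returns the reconstructed `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- unclass(spec)
  # named vectors must become objects, not name-less arrays
  if (!is.null(out$feature_fold_changes))
    out$feature_fold_changes <- as.list(out$feature_fold_changes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!is.null(raw$feature_fold_changes))
    raw$feature_fold_changes <- unlist(raw$feature_fold_changes)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(synthetic_spec, raw)
}
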