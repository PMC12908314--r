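---
title: "Co-occurrence network inference and robustness assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network inference and robustness assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cooccurnet)
```

## The problem

Gut-microbiome intervention studies routinely ask not only *which* taxa
change in abundance, but whether the *interaction structure* of the
community changes: does a probiotic make the ecosystem more densely
connected, and are its apparent hub genera stable conclusions or artifacts
of a handful of animals? `cooccurnet` implements the standard answer —
filtered all-pairs Spearman co-occurrence networks — together with the
resampling machinery needed to take the second question seriously at the
sample sizes these studies actually have (often four animals per arm), and
the surrounding association layers (group fold-change screening of
metabolites such as short-chain fatty acids, and star-annotated
taxa–metabolite–cytokine correlation matrices).

## The inference procedure

Starting from a genus-level count table with `n` samples in the group under
study:

1. **Filtering.** Taxa are retained when their *global relative abundance*
   (taxon total count / grand total count of the table passed in) is at
   least `filter_thres` (default 0.001) **and** their *prevalence* (fraction
   of samples with a strictly positive count) is at least
   `prevalence_thres` (default 0.10). The two conditions are applied as one
   conjunctive pass, so the filter is order-independent and idempotent.
   Because the "global" totals are those of the table given, filtering a
   single-group table uses that group's totals; `filter_taxa` on the pooled
   table first gives pooled-threshold semantics if preferred.
2. **Correlation.** For every unordered pair of retained taxa,
   `spearman_matrix()` computes the Spearman coefficient as the Pearson
   correlation of average-fractional ranks (ties receive average ranks,
   which matters for sparse count data). The default two-sided p-value uses
   the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
   degrees of freedom — the convention of mainstream implementations — with
   an opt-in exact permutation p (full enumeration of all `n!` orderings)
   for `n <= 9`. Pairs involving a taxon that is constant across samples
   have no defined rank correlation; they are reported as `degenerate`
   rather than raised as errors, because they are routine after heavy
   filtering at tiny `n`.
3. **Multiple testing.** Benjamini–Hochberg step-up adjustment is applied
   across the non-degenerate pairs of the table under analysis (per group,
   since each group's network is an independent inference; a pooled
   adjustment can be obtained by adjusting the concatenated p-vectors
   manually with `bh_adjust()`).
4. **Edge rule.** A pair becomes an edge when `|rho| > 0.30` (strict) and
   `q < 0.05` (strict). The graph is undirected; the edge weight is `|rho|`
   and the sign of the association is kept as a separate annotation.
5. **Descriptors.** `describe_network()` reports node/edge counts, density
   `2E / (N(N-1))`, mean degree `2E / N`, component structure among
   connected nodes, and the positive-edge fraction. Density and mean degree
   use *all* retained taxa in the denominator: an isolated node is a real
   outcome of the edge rule, and "connectivity" claims should not improve
   merely because isolated taxa are dropped. Because no single descriptor
   is *the* definition of connectivity, all candidates are emitted so any
   can be designated downstream.
6. **Threshold sensitivity.** `threshold_sensitivity()` rebuilds the network
   over an ascending `|rho|` grid (default 0.15–0.50 in steps of 0.05,
   `q_max` fixed) so the dependence of every descriptor on the cutoff choice
   is visible; the edge count is non-increasing in the cutoff by
   construction.

## Robustness at small n

Two complementary resampling analyses quantify how much of an inferred
network survives perturbation of the sample set:

- **Bootstrap (`bootstrap_networks`, B = 200).** Each replicate draws `n`
  samples with replacement *within the group being analyzed* and recomputes
  the full correlation–BH–edge-rule pipeline on the taxon set **frozen**
  from the observed filtered table — edge support is undefined if the node
  set drifts between replicates. Per pair, *edge support* is the fraction
  of replicates containing the edge; per taxon, *hub frequency* is the
  fraction of replicates in which it ranks among the top `k_hub = 3` nodes
  by degree (three, because three core genera are reported per network;
  boundary ties are all included, and zero-degree nodes never count as
  hubs). BH is re-run inside each replicate by default (`readjust_q =
  FALSE` reuses full-data q-values, for the cheaper variant). The
  *consensus network* keeps pairs with support at or above 0.70
  (inclusive), weighted by support, signed by the majority sign across
  supporting replicates (an exact tie is labelled positive).
- **Permutation null (`permutation_null`, P = 50).** Each replicate
  independently permutes, for every taxon row separately, the order of its
  values across samples. This destroys all cross-taxon association while
  preserving every taxon's marginal multiset exactly, and yields a null
  distribution of edge counts. The empirical p-value is the add-one
  estimator `(1 + #{null >= observed}) / (1 + P)`, which is unbiased under
  exchangeability and can never return zero.

Reproducibility: each replicate `r` is driven by a deterministic substream
seed derived from `(seed, r)`, so reports are bitwise reproducible and `B`
or `P` can be extended without disturbing earlier replicates.

### Behavior in the tiny-n regime

Two numerical facts about n = 4 deserve explicit statement, since the
package documents rather than hides them. First, any pair with a perfect
rank correlation has `p = 0` under the t approximation, so at n = 4 — where
a perfect ordering arises by chance with probability 1/12 per pair — the BH
step passes a substantial crop of chance edges, and nothing with `|rho| < 1`
can pass at all. Second, as a consequence, consensus-edge recovery of truly
correlated taxa is *not* monotone in sample size near the bottom: it is
slightly higher at n = 4 (perfect-rank artifacts are easy to reproduce
under resampling) than at n = 10 (where moderate correlations still cannot
clear BH across hundreds of pairs), before rising steeply through n = 20
and n = 40. The package's property tests assert monotone recovery over
{10, 20, 40} and treat the n = 4 point as the documented artifact it is.
Networks inferred from four samples per group should be read as
descriptive sketches; the bootstrap and permutation reports are exactly the
tools that make this limitation quantitative.

## The association layers

- `two_group_test()` gives the Mann–Whitney two-sided p by full enumeration
  of all `C(nA+nB, nA)` group assignments of the pooled midranks whenever
  `nA + nB <= 12` (enumeration on midranks remains a valid permutation test
  under ties, and returns exactly 1 for identical multisets), and the
  normal approximation with tie correction otherwise; a two-group
  Kruskal–Wallis (chi-square approximation) is available to mirror figure
  legends that use it.
- `fold_change_screen()` reports `mean(treatment) / mean(control)` per
  feature with the strict rule Up iff fold change > 1, and attaches the
  rank-test p without hard-coding a significance cutoff.
- `taxa_feature_correlation()` correlates taxon relative abundances with
  metabolite or cytokine concentrations cell by cell, adjusts across all
  cells of the matrix, and annotates stars from the **raw** p-value
  (`**` for p < 0.01, `*` for 0.01 ≤ p < 0.05), with q reported alongside —
  the annotation rule heatmap legends state is a raw-p rule.
- Metabolite–cytokine tests pool the samples of both groups (a single r per
  pair over n = 8 in the study-shaped setting).

## The synthetic generator

`generate_dataset()` draws data from a logistic-normal–multinomial model,
chosen over a Dirichlet–multinomial because it represents planted pairwise
correlations directly — and correlation recovery is exactly what the
pipeline must be tested on:

- Per taxon, a fixed baseline log-abundance `mu ~ N(0, base_log_sd = 1.5)`,
  spreading mean relative abundances over roughly three orders of magnitude
  as in real genus tables.
- Per sample, a latent Gaussian vector with unit variance, pairwise
  correlation `rho_latent` inside declared blocks and independence
  elsewhere, scaled by `latent_sd = 1` (log-scale biological variation of
  order one). Differential taxa have `log(fold_change)` added to the
  treatment group's latent mean.
- Softmax to a composition, multinomial counts at depth 20,000 (fixed by
  default so count-level correlations are not confounded by depth
  variation; a range can be given), optional independent Bernoulli dropout
  (`zero_inflation`) for extra sparsity.
- Metabolites and cytokines are lognormal variables tied to a chosen
  taxon's standardized latent score. A target Spearman `rho_s` is converted
  to the latent Pearson correlation through the bivariate-Gaussian relation
  `rho_s = (6 / pi) * asin(rho_p / 2)`, i.e. planted at
  `rho_p = 2 sin(pi rho_s / 6)`; because the lognormal transform is
  monotone, the population rank correlation of the observable equals the
  target. Concentration log-sds are 0.5 (metabolites) and 0.4 (cytokines),
  matching typical inter-individual CVs of roughly 40–50% for fecal SCFA
  and serum cytokine panels. Group fold changes for features are applied
  multiplicatively to the treatment samples.

`study_shaped_dataset()` packages the scale of the motivating design: 4
samples per group (NCD control vs NCD_Pro probiotic), 60 genera at depth
20,000 with 5% dropout, a five-genus co-occurring block (latent rho 0.8)
containing the control-flora genera, probiotic-enriched Lactobacillus and
Bifidobacterium (fold change 4) and depleted Clostridium (0.25), a
nine-acid SCFA panel in which butyrate and caproate fall to 0.276 of
control and isocaproate (4-MVA) rises 15.46-fold, a planted Clostridium →
4-MVA link at Spearman −0.7, and two cytokines halved by treatment and tied
to the same taxon.

### What the generator does and does not emulate

It reproduces compositionality (closure at fixed depth), realistic
abundance unevenness, plantable correlation blocks and group effects, and
rank-exact feature links. It does **not** model phylogenetic signal,
taxonomy-level aggregation error, sequencing error or chimeras, overdispersed
library sizes, or structured (abundance-dependent) zero inflation. Passing
recovery tests therefore demonstrates that the *procedure* behaves correctly
on data with the study's statistical shape, not that any particular real
dataset satisfies the model. Two emergent behaviors are worth knowing:
compositional closure can visibly attenuate a planted pair's count-level
correlation when a random baseline draw makes one member dominate the
composition (severe in very small tables, mild at 60 taxa); and in the
study-shaped preset the pooled (cross-group) metabolite–cytokine
correlations are dominated by the planted group shifts — a 15-fold
metabolite increase against halved cytokines pulls both pooled coefficients
negative at n = 8 regardless of the within-group links, a useful reminder of
what pooled correlations measure in two-group designs.

## Numerical choices

- Strict inequalities exactly as specified: `|rho| > 0.30`, `q < 0.05`,
  fold change Up iff `> 1`; consensus support is inclusive (`>= 0.70`).
- Coefficients within 1e−12 of ±1 are snapped to exactly ±1, so perfect
  monotone pairs give `rho = 1`, `p = 0` identically on every code path.
- The exact Mann–Whitney and exact Spearman options are full enumerations
  (`C(n, nA)` subsets and `n!` permutations respectively); the Spearman
  enumeration is capped at n = 9 where 362,880 permutations remain cheap.
- Degenerate inputs: constant taxa are set aside (`degenerate` pairs);
  zero-depth samples are kept as all-zero columns with a warning, because
  silently dropping samples would change `n` under resampling;
  `correlation_test()` on a constant vector is an error, since a scalar
  answer is expected there.
- Empty graphs are legal everywhere; density of a graph with fewer than two
  nodes is defined as 0, and the positive-edge fraction of an edgeless
  graph is `NA`.

## Worked example

```{r example, eval = FALSE}
ds <- study_shaped_dataset(seed = 7)
ncd <- filter_taxa(subset_by_group(ds$table, "NCD"))
net <- build_network(spearman_matrix(ncd), edge_rule())
describe_network(net)
permutation_null(ncd, P = 50, seed = 7)
consensus_network(bootstrap_networks(ncd, B = 200, seed = 7))
fold_change_screen(ds$metabolites, control = "NCD", treatment = "NCD_Pro")
```

Typical test problem sizes in this package are 15–60 taxa and 8–40 samples
with B = 200 bootstrap and P = 30–50 permutation replicates, and 10–200
simulated datasets per property; the full suite computes several hundred
thousand pairwise correlations in under a minute.

## Limitations

- Plain Spearman co-occurrence is blind to compositional coupling;
  compositionality-aware estimators (SparCC/SpiecEasi family) are out of
  scope by design, and negative-correlation results at low taxon counts
  should be interpreted with the closure effect in mind.
- Four samples per group support only the perfect-rank edges discussed
  above; the robustness reports quantify, but cannot repair, that limit.
- The permutation empirical p is discrete with resolution `1/(P+1)`; at
  P = 50 the smallest attainable value is 1/51 ≈ 0.0196.
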