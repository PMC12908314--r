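Package: cooccurnet
Title: Microbial Co-Occurrence Networks with Bootstrap and Permutation
    Robustness Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from taxon-by-sample
    count tables using filtered all-pairs Spearman correlation with
    Benjamini-Hochberg false discovery control, and quantifies network
    robustness at small sample sizes via sample bootstrapping (edge
    support, hub stability, consensus networks) and a permutation null
    for network connectivity with empirical p-values. Includes the
    associated two-group screening and taxa-metabolite-cytokine
    correlation layers, and a logistic-normal-multinomial synthetic data
    generator with planted correlation blocks, differential taxa and
    taxon-metabolite links for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
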