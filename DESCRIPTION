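Package: preynet
Title: Prey-Prey Protein and Domain Interaction Scoring from Aggregated
    IP-MS Pull-Downs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers binary prey-prey protein-protein interactions and
    underlying Pfam domain-domain interactions from collections of
    immunoprecipitation mass-spectrometry (IP-MS) pull-down experiments.
    Semi-quantitative spectral counts are aggregated across experiments
    and every prey pair is scored with four co-occurrence statistics
    (Sorensen set overlap, Pearson correlation of molecular-weight
    normalised abundances, a rank-proximity score, and a count-product
    score), which can be combined and thresholded into interaction
    networks and clique-derived protein complexes.  Includes GSEA-style
    running-sum, ROC/AUC and sliding-window benchmarking against
    reference interaction sets, propagation of pair scores onto domain
    pairs with a lambda co-occurrence index, and a synthetic pull-down
    generator with planted complexes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
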