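Package: phylosf
Title: Slow-Fast Site Stripping, Topology Tests and Dollo Gene-Content
    Analysis for Deep Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream inference tools for deep phylogenomic studies of
    lineages prone to long-branch attraction, such as fast-evolving
    zoosporic fungi. Implements per-site posterior-mean substitution rate
    estimation under a discrete-gamma Poisson model, the slow-fast
    procedure (progressive removal of the fastest-evolving alignment
    sites with bootstrap support curves for named clade hypotheses),
    RELL-based approximately-unbiased (AU) topology tests, Dollo
    parsimony reconstruction of ancestral gene content with gain/loss
    dynamics, and comparative statistics on binary presence/absence
    ortholog profiles (distances, principal coordinate analysis, Ward
    clustering). A synthetic-data generator produces trees, alignments
    with gamma rate heterogeneity and long-branch scenarios, and
    single-gain irreversible-loss trait matrices with known ground
    truth, so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
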