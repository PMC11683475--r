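Package: ovisatlas
Title: Multi-Omics Prioritization of Regulatory Variants for Complex Traits in Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit that moves from genotype,
    epigenome and expression matrices to a ranked set of candidate causal
    regulatory variants. Implements chromatin-state segmentation with a
    multivariate Bernoulli hidden Markov model, tissue-specificity scoring
    (tau), windowed Weir-Cockerham FST, nucleotide diversity and XP-EHH
    selection scans, mixed-linear-model genome-wide association with
    kinship correction, interval-overlap fold enrichment with a
    permutation null, and a prioritization funnel intersecting significant
    associations with selective sweeps, open chromatin, H3K27ac peaks and
    topologically associating domains. Ships a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
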