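Package: enamelmap
Title: Spatial Proteome Mapping of Forming Tooth Enamel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free quantitative proteome mapping over a diced tooth-crown
    sample grid. Aggregates peptide-level peak areas to volume-normalized
    top-3 protein abundance maps, computes spatial phospho-occupancy
    (P:P+NP) maps for isoform-discriminating marker peptides validated by
    in-silico tryptic digestion, defines developmental-stage groups of
    sample locations by PCA and Euclidean hierarchical clustering, and tests
    per-protein differential abundance across groups by permutation ANOVA
    with Benjamini-Hochberg FDR control and a hypergeometric
    over-representation test. A seeded synthetic-data generator emulates the
    statistical structure of a 21-location diced-crown experiment so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
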