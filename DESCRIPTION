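Package: hbcgm
Title: Haplotype-Based Computational Genetic Mapping with Gene-Wise Permutation FDR
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Whole-genome haplotype-block association mapping for panels of
    inbred strains. Consecutive-SNP windows partition strains into haplotype
    groups, each partition is tested against strain-level trait means by
    one-way ANOVA, and gene-level p-values are taken as the minimum over
    overlapping blocks. A permutation-derived gene-wise false discovery rate
    filter removes highly polymorphic genes that match shuffled phenotypes by
    chance, and filtered results from related traits are integrated into a
    composite sum of -log10(p) scores for gene ranking. Includes derivation of
    opioid adaptation phenotypes (percent maximal possible effect, ED50 and
    tolerance fold change from cumulative dose-response curves, opioid-induced
    hyperalgesia as percent decrease from baseline threshold, percent weight
    change, naloxone-precipitated jumping), a synthetic strain-panel simulator
    with planted causal effects for end-to-end validation, and a command-line
    interface covering simulation, phenotype derivation, mapping, FDR
    filtering and integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
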