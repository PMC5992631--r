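Package: introrad
Title: Introgression Detection and Phylogenetic Discordance Analysis for RAD Loci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting introgression and dissecting gene-tree/species-tree
    discordance in short-read RAD-locus data. Implements ABBA-BABA (Patterson's D)
    test batteries with locus-bootstrap Z-scores, all-combination individual
    permutation and Holm-Bonferroni correction; PyRAD-style locus and individual
    quality filters with unlinked-SNP extraction; distance-based concatenation and
    quartet-frequency multispecies-coalescent species-tree inference; and naive
    binning of loci into supergenes to expose concatenation bias under introgression.
    A built-in multispecies-coalescent simulator with admixture pulses, Jukes-Cantor
    sequence evolution and ddRAD-style missingness provides ground-truth data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
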