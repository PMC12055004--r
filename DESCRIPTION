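Package: coevotree
Title: Mirrortree Coevolution Analysis from Protein Distances and Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects interspecies protein coevolution with the mirrortree
    approach: pairwise evolutionary distances are estimated from aligned
    protein sequences by maximum likelihood under the Jones-Taylor-Thornton
    (JTT) amino-acid substitution model with uniform site rates, or extracted
    as patristic distances from phylogenetic trees; distance matrices for two
    gene families are correlated over their common organisms, correlations
    are mapped through Fisher's r-to-z transformation, and pairs of
    correlations are contrasted with a z statistic against panels of control
    genes. Includes neighbor-joining reconstruction, column-bootstrap
    standard errors for distances, presence/absence co-occurrence scoring
    for phylogenetic profiles, and a synthetic-data generator that evolves
    coevolving gene trees and JTT protein alignments along a shared species
    tree with a tunable branch-rate correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
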