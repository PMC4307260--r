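Package: samefam
Title: Duplication, Expression and Sequence Divergence Analysis of the
    SAMe Methyltransferase Superfamily in a Domesticated Plant and Its
    Wild Variety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for comparative analysis of a gene
    superfamily between a domesticated plant variety and its wild
    relative, modelled on the S-adenosyl-L-methionine-dependent
    methyltransferase (SAMe) superfamily of Lonicera japonica. Provides
    simulation of two-variety gene-family panels with known subgroup
    structure and planted variants; Smith-Waterman local alignment with
    Karlin-Altschul significance; neighbor-joining phylogenetics with
    bootstrap majority-rule consensus and tree-based subgroup
    classification; reciprocal-best-hit orthology and copy-number
    tables; RPKM expression contrasts and comparative-Ct
    quantification; a pileup-based SNP/indel filter cascade with
    Fisher contingency testing; and amino-acid-change annotation of
    ortholog pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
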