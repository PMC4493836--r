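Package: methaprimer
Title: Degenerate Primer Design and Amplicon Validation for Methanogenesis Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for creating and validating degenerate PCR primers
    targeting methanogenesis marker genes (mcrB, mcrG, mtaB, mtbA and
    relatives). Provides IUPAC ambiguity-code sequence algebra, detection of
    conserved windows in nucleotide alignments and minimal-degeneracy primer
    pair enumeration, neighbor-joining partitioning of hypervariable gene
    families into designable clusters, in-silico PCR with per-primer mismatch
    budgets and product-length tolerance, a FLASH-like paired-end read merger,
    a six-frame translated Smith-Waterman search with Karlin-Altschul
    E-values, the primer-sensitivity statistic, simplified phylogenetic
    placement of inferred peptides onto a reference tree with mass trimming
    and PhyloXML fat-tree export, and seeded synthetic-data generators
    (gene families, amplicon libraries, reference sets) with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
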