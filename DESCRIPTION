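Package: fibhome
Title: Extraction and Comparative Analysis of Silkworm Fibroin Heavy-Chain Gene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with complete fibroin heavy-chain (FibH) gene
    loci from assembled silkworm genomes. Extracts the full gene plus 5 kb
    flanks from chromosome FASTA via 20-bp terminal barcodes on either strand,
    decomposes the gene into exons, intron, terminal non-repetitive blocks and
    the GC-rich repetitive core, scans degenerate IUPAC motifs and NdeI
    amorphous-region delimiters, computes pairwise and group identity with an
    anchored affine-gap aligner, extracts and classifies the canonical
    differential sequences around the GGTGCT core unit, partitions strains
    into identical-allele pedigree families with UPGMA/Newick export, and
    scans flanking regions for cis-regulatory elements. A seeded synthetic
    cohort generator emulating wild, local and improved silkworm FibH loci
    makes the whole pipeline testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
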