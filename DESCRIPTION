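Package: poolsplit
Title: Genotype-Free Demultiplexing of Pooled Single-Cell RNA-Seq by an
    Allele-Fraction Mixture Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Demultiplexes pooled single-cell RNA-seq samples without
    external genotypes. SNV-level reference and alternative allele counts
    per cell barcode are modelled as a finite mixture over donors with an
    extra doublet component; per-cluster alternative-allele fractions are
    fitted by expectation-maximization with multiple random restarts, cells
    are assigned by posterior probability, doublets are flagged via
    cross-assignment likelihood, and a minimal set of distinguishing
    variants (presence/absence genotype patterns) maps clusters back to
    donors when donor genotypes are available. Includes a
    genotype-likelihood-driven count simulator (Hardy-Weinberg donors,
    full-sibling pairs, merged-barcode doublets) and evaluation utilities
    (TPR, FDR, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    vcfR,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Biostrings,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
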