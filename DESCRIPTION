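Package: cryscreen
Title: Targeted Amplicon Screening for Cry1F Resistance Alleles in Fall
    Armyworm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for DNA-based monitoring of Bacillus thuringiensis
    Cry1F resistance alleles in the fall armyworm ABC transporter gene
    SfABCC2 from tiled (Hi-Plex style) amplicon sequencing. Simulates
    tiled amplicon reads for diploid samples, genotypes a known 2-bp
    insertion by 10-mer flank matching with mismatch tolerance, applies
    depth/allele-depth/frequency filters to multi-sample variant calls,
    classifies variants against a gene model (missense, nonsense,
    frameshift, in-frame indel, splice region), predicts Cry1F resistance
    phenotypes from truncating alleles including trans-heterozygous
    complementation, and computes cohort statistics: allele frequencies,
    per-location carrier summaries, cross-method genotype concordance,
    genotype PCA and a per-site association scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
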