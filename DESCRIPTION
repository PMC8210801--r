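Package: genload
Title: Genetic Erosion and Genetic Load Analysis from Genotype Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying genetic erosion in
    small and fragmented wildlife populations from low-coverage whole-genome
    resequencing data. Computes genotype likelihoods under the SAMtools error
    model, maximum-likelihood allele frequencies, polymorphism and
    Hardy-Weinberg filters, and posterior genotype calls; site-frequency-
    spectrum diversity estimators (Watterson's theta, per-individual
    heterozygosity, effective population size from interspecific divergence);
    IBS-based kinship, inbreeding coefficients and covariance PCA; windowed
    Hudson Fst, Dxy and Z(Fst) outlier scans with Fu and Li's neutrality
    statistics; variant impact classification and the potential-load (Load_P)
    and realized-load (Load_R) statistics with Welch tests; and alignment-based
    mitogenome-style diversity statistics. Includes a forward Wright-Fisher
    simulator with selection, selfing and population splits that generates
    synthetic truth bundles (VCF/GFF3/FASTA/pileup) for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
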