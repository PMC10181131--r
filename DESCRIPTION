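Package: tetrafinger
Title: SNP Fingerprinting and Dosage Genotyping for Autotetraploid Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building SNP-marker fingerprinting panels for
    autotetraploid crops such as potato. Covers cohort-VCF marker discovery
    (high-quality SNP filtering, SNP density and SNP-rich windows, selection of
    assay-ready "perfect" SNPs), allele dosage calling from two-channel
    allele-specific PCR fluorescence via order-constrained Gaussian mixtures,
    per-marker dosage statistics (mean A frequency, observed heterozygosity,
    polymorphic information content), PIC-thresholded fingerprint construction,
    and variety-identity analysis (synonym and homonym detection) from
    Euclidean genotype distances and UPGMA dendrograms. A synthetic-data module
    generates dosage matrices, fluorescence signals, and toy cohort VCFs with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    vcfR,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
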