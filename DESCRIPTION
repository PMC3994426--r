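Package: triconcord
Title: Triple-Concordance Genomic Aberration Analysis of Paired Tumor/Normal SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired tumor and adjacent-normal SNP-array
    cohorts: per-SNP quality control (minor allele frequency, call rate, exact
    Hardy-Weinberg test), per-patient copy-number run detection and cohort-level
    recurrent copy-number-variation region calling, McNemar-Bowker symmetry
    testing of paired genotypes, loss-of-heterozygosity recurrence analysis, and
    the intersection of the three arms into candidate biomarker loci. Includes a
    synthetic paired-cohort generator with planted ground truth, calibration and
    recovery diagnostics, and readers/writers for the delimited-text, VCF and
    BED artifacts the pipeline exchanges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
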