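Package: pestgs
Title: Image-Based Phenotyping, GWAS, and Genomic Selection for Pest Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of an integrated
    pest-resistance breeding pipeline: synthetic leaf images with known damage
    fractions, a small convolutional network that scores pest damage as binary
    and continuous (0-5) traits, aggregation of image scores into per-accession
    phenotypes with distributional statistics and a Spearman footrule
    permutation test against a tree ordering, an exact linear mixed model
    genome-wide association scan with windowed F_ST, nucleotide diversity and
    LD statistics, and machine-learning genomic selection over GWAS-ranked,
    LD-pruned marker subsets. Cohorts are simulated with tunable population
    structure, linkage disequilibrium, and planted additive QTLs so that every
    stage of the pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    ape,
    vcfR,
    jsonlite,
    glmnet,
    e1071,
    ranger,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
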