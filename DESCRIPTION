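Package: egrmpca
Title: Expected Genetic Relationship Matrices and Divergence Statistics
    for Population Stratification PCA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds empirical genetic relationship matrices (GRMs) from
    genotype counts and their exact mathematical expectation (the EGRM)
    from per-population allele frequencies, computes the block-structured
    eigen-decomposition that separates inter- from intra-population
    variance, and quantifies population divergence with the F_PC, F_PC*
    and d^2 statistics together with Wright's F_ST. Includes a
    Hardy-Weinberg multi-population genotype simulator, minor-allele
    frequency binning, replicate convergence experiments, plain-text
    readers and writers for frequency tables, genotypes (TSV and PLINK
    traw), square relationship matrices and eigenvec/eigenval files, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
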