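Package: indelscreen
Title: Pooled-PCR Screening Design and Population Genetics for Low-Frequency InDels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for screening rare insertion/deletion polymorphisms in
    large livestock cohorts and characterising them downstream. Implements
    the mathematical-expectation (ME) pooled-PCR design (optimal pool size,
    predicted and realised reaction counts, savings accounting), single-locus
    population-genetic statistics (allele frequencies, Hardy-Weinberg testing,
    heterozygosity, effective allele number, polymorphism information content),
    two-locus EM haplotype frequency estimation with D' and r-squared linkage
    disequilibrium, genotype-trait association testing (t-test, one-way ANOVA
    with significance letters, fixed-effect genotype + sex linear model), and
    qPCR expression statistics (2^-ddCt relative quantification, Pearson
    correlation with exact p-values). A synthetic-herd generator reproduces
    the statistical structure these stages assume so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
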