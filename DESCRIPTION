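Package: ivypopgen
Title: Multilocus Population Genetics of a Highly Selfing Annual Plant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of the multilocus population-genetics
    workflow used to characterize North American populations of the selfing
    vine Ipomoea hederacea from phased Sanger haplotypes: silent-site
    nucleotide diversity (Watterson and pairwise theta), neutrality tests
    (Tajima's D, Fu's Fs, Ramos-Onsins and Rozas's R2) with coalescent nulls
    conditioned on the observed number of segregating sites, hierarchical
    F-statistics and AMOVA with permutation significance, Nei's distance and
    isolation-by-distance Mantel tests, per-SNP FST outlier comparison
    against a single-locus leaf-shape polymorphism, equilibrium selfing-rate
    estimation, simplified Bayesian admixture clustering with inbreeding, and
    Mendelian inference of maternal leaf-shape genotypes from selfed progeny
    arrays. A coalescent engine with structured, growing, and partially
    selfing demographies generates synthetic datasets with the statistical
    structure of the original sampling design, so the whole pipeline is
    exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    geosphere,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
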