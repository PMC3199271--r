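Package: paraconv
Title: Paralog Gene-Conversion Scans and Polymorphism Analysis for Duplicated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of tandemly duplicated genes
    such as the cytochrome P450 CYP1A1/CYP1A2 pair. Implements a
    sliding-window maximum-likelihood scan that contrasts the two unrooted
    quartet topologies expected with and without inter-paralog gene
    conversion (HKY85 likelihoods via Felsenstein pruning), a battery of
    within-species polymorphism statistics (nucleotide diversity, segregating
    sites, Tajima's D, Nei-Gojobori synonymous/nonsynonymous diversity and
    dN/dS, the HKA polymorphism-divergence test, Hardy-Weinberg chi-square,
    and null-allele annotation from coding haplotypes), CpG dinucleotide
    accounting with CpG-degeneration SNP classification, and simulators
    (quartet histories with known conversion tracts; Kingman coalescent
    samples with CpG-context hypermutability and tunable functional
    constraint) that generate test data with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ape,
    Matrix,
    withr
Config/testthat/edition: 3
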