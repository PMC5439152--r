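Package: hybridimpute
Title: Hybrid Heuristic and Hidden Markov Model Genotype Imputation for
    Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes missing biallelic genotypes in pedigreed (livestock)
    populations by combining pedigree-based heuristics (Mendelian inheritance
    rules, single-locus segregation analysis, long-range phasing with surrogate
    parents, and haplotype-library imputation over multi-length cores) with a
    Li-Stephens haplotype-copying hidden Markov model in the style of MaCH.
    The heuristic stage resolves most alleles for well-connected individuals
    and builds an accurate haplotype library; the HMM imputes whatever the
    heuristics leave unresolved, in a haploid variant for pre-phased gametes
    and a diploid variant for unphased genotypes, with per-interval crossover
    and per-marker error parameters re-estimated across Monte-Carlo iterations.
    Also included are a coalescent simulator with piecewise-linear demography,
    a pedigree gene-dropping simulator with per-centimorgan crossovers,
    low-density panel masking, and allele-dosage accuracy evaluation
    (animal-wise and marker-wise Pearson correlations with minor-allele
    frequency bins and ancestor-genotyping categories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
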