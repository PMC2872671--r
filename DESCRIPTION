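Package: mycopop
Title: Multilocus Sequence Genotyping and Population Genetics of
    Dikaryotic Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multilocus sequence data from dikaryotic
    fungal specimens, where direct sequencing yields IUPAC-coded
    heterozygous sites.  Reads and validates per-locus alignments,
    classifies alignment columns (substitutions, indel tracks), collapses
    sequences into genotypes and computes unbiased genotypic diversity,
    partitions polymorphism between divergent lineages (fixed, private
    and shared sites), builds maximum-parsimony genealogies with Fitch
    scoring, consistency/retention indices, nonparametric bootstrap,
    partition-homogeneity and monophyly-constraint tests, phases dikaryon
    genotypes into haplotypes by expectation-maximisation, and tests the
    mode of reproduction with the index of association and pairwise-locus
    phylogenetic compatibility.  Includes a seeded synthetic-data
    generator emulating divergent lineages, indel tracks and clonal
    versus sexual reproduction so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
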