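Package: milkQTL
Title: Pedigree-Based Candidate-Gene Association Analysis for Milk
    Production Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association analysis of candidate-gene SNPs and haplotype
    combinations with quantitative milk production traits in half-sib
    dairy cattle designs. Builds the pedigree numerator relationship
    matrix by the tabular method, fits the animal model by solving
    Henderson's mixed-model equations with user-supplied variance
    components, reports least-squares means with Bonferroni-adjusted
    pairwise comparisons and compact-letter displays, and decomposes
    genotype effects into additive, dominance and allele-substitution
    components. Includes EM haplotype-frequency estimation from
    unphased genotypes, Lewontin D' with likelihood confidence
    intervals, Gabriel-style haplotype-block detection, per-individual
    diplotype assignment, position-weight-matrix scanning for
    allele-dependent transcription-factor binding sites, and a
    synthetic half-sib study generator with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
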