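Package: esterdeg
Title: Differential Expression and Meiotic Genetics of Yeast Esterase-Gene Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the computational analysis of
    multiple esterase-gene-deletion experiments in wine yeast: RPKM
    normalization of gene-level read counts with correction of overlapping
    open reading frames, differential-expression calling with a Levene-gated
    switch between one-way ANOVA and Kruskal-Wallis tests, hypergeometric
    Gene Ontology enrichment, complete-linkage clustering of protein-protein
    interaction confidence-score matrices with size and score retention
    rules, histone-modification enrichment scoring of regulated gene sets,
    analytic expectations and seeded simulation of multi-locus meiotic
    segregation with genotype-dependent spore viability, and the metabolite
    and sensory statistics used in such studies (control normalization,
    Kruskal-Wallis with rank-based LSD post hoc, two-way ANOVA with Tukey
    HSD, exact triangular-test binomial probabilities, and Wilcoxon
    descriptor comparisons). A seeded synthetic-data generator emulates
    every input the pipeline consumes so all stages are testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    tools,
    utils
Suggests:
    car,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
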