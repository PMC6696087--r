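Package: twinstrat
Title: Trait-Stratified Genetic Association Analysis for Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-stage, trait-stratified genetic association workflow for
    twin cohorts. Ordinal diagnostic-interview item scores are aggregated
    into cumulative severity scores for five behavioural traits; per-SNP
    quantitative trait association screens each twin subgroup for
    quantitative trait nucleotides (QTNs); case-control allelic tests then
    contrast severity-extreme (first and fourth quartile) cases against
    unrelated controls, with Bonferroni and Benjamini-Hochberg correction
    and odds-ratio contrasts between quartiles; significant SNPs are mapped
    to nearest genes and tested for risk-gene-set over-representation by
    the hypergeometric upper tail. A seeded synthetic twin-cohort generator
    (Hardy-Weinberg founders, Mendelian dizygotic transmission, identical
    monozygotic genomes, additive liability model with shared environment,
    liability-threshold diagnosis) provides ground-truth data so every
    stage is testable without restricted genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
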