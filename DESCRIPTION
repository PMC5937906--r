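Package: falconer
Title: Single-Locus SNP Association and Falconer Effect Decomposition for
    Pediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Candidate-SNP association analysis for child anthropometric
    cohorts: LMS-method BMI z-scores, IOTF-style weight-category
    classification and HOMA-IR; allele and genotype frequencies with
    asymptotic and exact Hardy-Weinberg equilibrium tests; Pearson
    chi-square case-control association; genotype-stratified phenotype
    contrasts with Dunn-Bonferroni adjustment; and the Falconer
    single-locus additive/dominance effect decomposition with
    dominance-type classification and effect-size grading, exposed as a
    classed model fit with the usual methods. Includes a seeded synthetic
    cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
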