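Package: snrnascreen
Title: Discovery Analysis for Disease Variants in Small Nuclear RNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for screening spliceosomal small nuclear RNA
    (snRNA) genes for disease-causing variants in rare-disease cohorts.
    Prioritizes putatively functional snRNA genes from regulatory-element
    overlap, hypermutability and nomenclature evidence; summarizes small
    RNA-seq signal to assess detectability; extracts de novo and biallelic
    candidate events from trio, duo and singleton pedigrees with depth,
    allele-fraction and population-frequency filters; tests gene-level
    carrier burden with exact Fisher tests, a minimum-carrier retention
    rule and Bonferroni correction; scores variants with a
    hypermutability-adjusted ACMG evidence scheme; compares categorical
    clinical features between variant groups; and fits covariate-adjusted
    linear models to splicing (PSI) and methylation (beta) matrices with
    probe-pattern classification. A synthetic-cohort generator with known
    ground truth makes every stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
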