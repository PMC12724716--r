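Package: ccmito
Title: Mito-Nuclear Systems Genetics for Collaborative Cross Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-based mitochondrial genotype imputation for inbred
    strain panels with maternally inherited mitochondrial DNA, linear-model
    trait-GWAS and trans-eQTL scans against mitochondrial markers with
    permutation-based family-wise error control, rank aggregation and
    preranked gene-set enrichment, two-dendrogram comparison of trait and
    sequence clusterings via entanglement and cophenetic correlation, and
    dual-genome candidate-gene overlap. Ships a synthetic Collaborative
    Cross-like cohort generator with a planted-effect truth registry so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
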