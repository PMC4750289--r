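Package: oncofuzz
Title: Fuzzy-Logic Integration of Mutation, Expression and Copy-Number Data
    into Gene Activity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates somatic mutation calls, gene expression and copy-number
    measurements into per-sample, per-gene activity scores in [-1, 1] using a
    Mamdani-style fuzzy inference system with an editable rule base written in
    a subset of the IEC 61131-7 Fuzzy Control Language.  Positive scores
    indicate oncogene-like gain of function (GoF), negative scores indicate
    tumor-suppressor-like loss of function (LoF).  Includes per-gene fitting of
    expression membership functions from tertiles, hotspot-recurrence calling,
    gene-level GoF/LoF classification with a mutation-frequency filter,
    evaluation utilities (Mann-Whitney ROC AUC, paired bootstrap AUC
    comparison, two-component Gaussian-mixture drug-sensitivity thresholds),
    and a seeded synthetic-cohort simulator with planted driver genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
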