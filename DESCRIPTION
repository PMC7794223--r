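Package: extendscore
Title: Telomerase Enzymatic Activity Estimation from Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates telomerase enzymatic activity per sample from gene
    expression using a 13-gene signature and a two-component iterative
    rank-sum score (EXTEND). Includes the signature-derivation pipeline
    (one-sided differential expression, anchor-gene co-expression threshold
    scan with percentage-difference elbow selection, and constituent
    augmentation), downstream analyses (stemness index correlation,
    gene-label permutation empirical p-values, cell-cycle phase grouping
    for single cells, pairwise group comparisons), a synthetic bulk and
    single-cell cohort generator with planted ground truth, and a command
    line interface. Scoring is rank-based and therefore insensitive to
    expression units and scaling normalisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
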