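Package: crossnmf
Title: Cross-Disease Patient Subtyping by Convex Non-Negative Matrix
    Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies shared molecular subgroups between two diseases
    from gene expression data. Patient log2 fold-change matrices are
    bi-clustered with convex non-negative matrix factorization, the
    factorization rank is chosen by the cophenetic correlation of a
    consensus matrix, gene clusters are refined with Kruskal-Wallis and
    Dunn post-hoc filtering, per-cluster differentially expressed gene
    modules are derived against controls, a related cluster pair between
    the two diseases is selected by hypergeometric pathway enrichment
    against reference gene lists, and the resulting same-direction
    candidate genes are evaluated with cross-validated logistic
    regression. A synthetic-data generator with planted subgroup
    structure supports end-to-end evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
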