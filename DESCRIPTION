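Package: emtsig
Title: Supervised Selection of Epithelial-Mesenchymal Hybrid Phenotype Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for discovering gene signatures that separate epithelial,
    hybrid epithelial/mesenchymal and mesenchymal drug-resistant cancer cell
    lines from bulk log2 expression data. Implements microarray-style
    preprocessing (low-intensity filtering, quantile normalization,
    probe-to-gene summarization, replicate averaging), recurrence-based
    differential expression across resistant-versus-parental comparisons,
    three supervised EMT-gene selectors (expression cut-off, linear-SVM
    hyperplane coefficients over pairwise phenotype problems, and
    dendrogram-cut expression-profile clustering) with their consensus
    intersection, phenotype-space mapping by PCA and hierarchical clustering,
    and hypergeometric/EASE over-representation analysis with a
    fold-enrichment comparison rule. Ships a synthetic cohort generator that
    emulates the eight-cell-line, two-replicate study design with planted
    phenotype markers, recurrently deregulated resistance genes and a
    cell-line-of-origin batch effect, providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    e1071,
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
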