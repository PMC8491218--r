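Package: pesig
Title: Pathway-Extended Gene Expression Signatures for Drug Response
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives multi-gene expression signatures that classify tumour
    samples as sensitive or resistant to kinase inhibitors. Starting from a
    curated seed list of genes implicated in the response to a drug, each
    gene's expression (and optionally copy number) is related to cell-line
    GI50 through a multiple-factor-analysis correlation angle; the gene pool
    is then expanded through a pathway interaction network (SIF format) to
    one- and two-node distant neighbours that also correlate with GI50.
    Gaussian-kernel support vector machine signatures are derived from the
    qualified pool by forward feature selection over a (C, sigma) grid,
    validated on independent cohorts by Matthews correlation coefficient,
    dissected by leave-one-gene-out importance, and combined into
    AUC-weighted voting ensembles. A synthetic-data module generates
    cell-line panels, interaction networks and patient cohorts with planted
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
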