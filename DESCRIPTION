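Package: idssim
Title: LncRNA Functional Similarity from Improved Disease Semantic Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes lncRNA functional similarity from known lncRNA-disease
    associations and a disease vocabulary organised as a tree-numbered
    hierarchy (such as the MeSH disease category). Disease semantic
    similarity is derived from per-term semantic values on each disease's
    ancestor DAG under three selectable models: plain decay (LNCSIM1),
    information content (LNCSIM2), and decay augmented by an
    information-content contribution factor that rewards rare, specific
    terms (IDSSIM). Functional similarity between lncRNAs is the
    best-match average over their disease groups. The package also
    provides the WKNKN (weighted k nearest known neighbors) association
    pre-completion step, a repeated five-fold cross-validation protocol
    with threshold-swept ROC/AUC, significant potential-association
    network extraction, and a synthetic vocabulary/association generator
    with planted block structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
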