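Package: fgie
Title: Information Extraction for Cancer Functional-Genomics Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts structured descriptions of gene-perturbation experiments
    from biomedical abstracts. Provides a four-category annotation schema
    (perturbing action, context, effect, phenotype) with per-category assertion
    labels, readers and writers for MAE-style standoff XML and a JSON
    interchange format, a BIO sequence codec, a multi-head transformer
    named-entity tagger trained with class-balanced cross-entropy, a pairwise
    token-embedding link-prediction model with an auxiliary same-tag objective,
    the matching evaluation protocol (document-level splits, per-head
    precision/recall/F1, a sentence co-occurrence baseline, k-fold
    cross-validation), a generator of gold-annotated synthetic abstracts, and
    case-study aggregation of gene-perturbation records into experimental
    context groupings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
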