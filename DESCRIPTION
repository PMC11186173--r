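Package: igensigrx
Title: Integral Genomic Signature Modeling of Binary Therapeutic Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: White-box prediction of binary therapeutic response (pathological
    complete response versus non-response) from high-dimensional binary
    multi-omics features. Feature weights are phi coefficients against the
    response label; feature redundancy is penalized per patient with
    Otsuka-Ochiai co-occurrence similarity estimated from a large unlabeled
    reference cohort, gated by Ward (ward.D2) hierarchical clustering with a
    hybrid dynamic tree cut. Class scores follow the effective-weight /
    effective-feature-number formulation and the final score is the signed
    distance to a Youden-index dividing line. Includes a synthetic cohort
    generator with planted redundant predictive feature blocks, a feature-error
    robustness harness, and an L1-regularized logistic baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
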