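Package: repdx
Title: TCR Repertoire Diversity, Sharing and Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Repertoire", "Maintainers", email = "maintainers@repdx.dev",
           role = c("aut", "cre"))
Description: Analytics for bulk TCR-beta CDR3 clonotype tables in a
    tumor / adjacent non-tumor tissue / peripheral blood study design:
    clonotype diversity (Shannon entropy, top-k clonality), cross-tissue
    clonotype sharing and clonal-expansion statistics, public-clonotype
    detection, V/J/VJ gene-usage matrices with differential-usage testing
    and PCA, a ROC/fold-change marker screen for discriminative VJ
    pairings, and a repeated equal-sampling LASSO logistic-regression
    diagnostic harness. Includes a synthetic multi-tissue repertoire
    generator with recorded ground truth so the full pipeline is testable
    without access to a patient cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
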