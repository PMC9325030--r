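Package: lncPairRisk
Title: Expression-Level-Independent Prognostic Signatures from Immune-Related lncRNA Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tumour prognostic signatures from rank-based 0/1 indicators
    of immune-related lncRNA pairs, so that the resulting risk score does not
    depend on absolute expression levels or between-sample normalisation.
    Provides immune-related lncRNA screening by co-expression, moderated-t
    differential expression, construction and filtering of the binary pair
    indicator matrix, repeated cross-validated LASSO-Cox selection with
    frequency thresholding, greedy AUC-guided Cox model search, risk scoring
    with an AIC-derived cut-point on the time-dependent ROC curve,
    Kaplan-Meier and log-rank risk-group comparison, downstream
    clinicopathological and immune-infiltration association statistics, and a
    synthetic cohort generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
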