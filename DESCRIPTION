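Package: flcindex
Title: Free Light Chain and IgG Indices for Intrathecal Synthesis
    Diagnostics in Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes cerebrospinal-fluid/serum quotients, the kappa and
    lambda free light chain (FLC) indices and the IgG-quotient-based
    kappa/lambda IgG indices from paired CSF/serum immunochemistry panels,
    with detection-limit substitution for censored CSF FLC values.
    Provides tie-corrected nonparametric rank tests (Mann-Whitney U with
    exact small-sample p, Kruskal-Wallis, Dunn post-hoc with Bonferroni
    adjustment, Spearman correlation with pairwise-complete matrices),
    ROC analysis with Youden cut-off selection and the five standard
    diagnostic performance metrics, exact integer reconstruction of
    confusion matrices from rounded published metrics, and a seeded
    Gaussian-copula log-normal simulator of a 76-patient MS/control
    cohort stratified by oligoclonal band pattern, so the full analysis
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
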