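Package: sigscore
Title: Gene-Signature Biomarker Scoring and Evaluation for Transcriptomic Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-sample gene-signature biomarker scores from bulk or
    single-cell expression matrices: a within-sample two-set Welch t-score
    contrasting a signature's up- and down-regulated members (a repression
    score), and mean-expression scores over up-regulated gene sets (activation
    scores). Provides the statistical stack used to evaluate such biomarkers:
    quantile normalization, Wilcoxon rank-sum group tests, ROC curves with
    tie-corrected AUC, DeLong's paired test for correlated AUCs, univariate
    and multivariate linear severity models, score-threshold stratification,
    and signature-positivity calling in single cells. Includes calibrated
    synthetic bulk and single-cell data generators with planted repression
    and activation programs, and a command-line interface mirroring the
    scoring app contract (Results.csv plus group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
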