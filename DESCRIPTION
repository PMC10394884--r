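Package: cpgmark
Title: CpG Methylation Biomarker Discovery with Resampled Penalized Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover and evaluate minimal CpG methylation
    signatures of a binary mutation status from Illumina 450K-style
    beta-value matrices. Implements empirical-Bayes moderated t-tests for
    differential methylation with Benjamini-Hochberg correction and
    genomic-region enrichment, a pan-negative comparison that removes
    samples carrying confounder co-mutations, a signature-selection engine
    that nests feature screening and elastic-net logistic regression inside
    repeated stratified random sampling across training-set sizes with
    confidence-interval based size selection and per-CpG inclusion
    probabilities, classifier evaluation (confusion metrics, ROC/AUC,
    Bayes posterior probabilities, PCA separation), cis
    methylation-expression correlation within a flanking window, and
    per-CpG survival cut-point analysis by maximally selected log-rank
    statistics with permutation p-values. A synthetic-cohort generator
    with planted case/control methylation structure, confounder mutations,
    linked expression and survival makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    knitr,
    limma,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
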