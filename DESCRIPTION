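Package: gipipe
Title: Genomic Instability Signatures and Tumor Immune Microenvironment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for RNA-based genomic-instability and immunogenicity
    analysis of bulk breast tumor expression profiles. Provides
    nearest-centroid classification of TP53 functional status (Mut-like vs
    WT-like), homologous recombination deficiency (HRD-high vs HRD-low) and
    global immune classes (Adaptive-Enriched, Innate-Enriched, Immune-Quiet);
    the any-genomic-instability (AGI) composite; median-based immune cell
    scores with third-quartile dichotomization; relative frequency difference
    (RFD) estimation via identity-link binomial GLMs with explicit
    non-convergence reporting; Welch t tests and differential immune-score
    models with Benjamini-Hochberg correction; and Kaplan-Meier / Cox
    proportional hazards recurrence analysis of immune classes stratified by
    AGI status. Includes a synthetic cohort generator emulating the
    statistical structure these analyses assume, so every stage is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
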