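Package: glycopattern
Title: Dose-Response Pattern Analysis for Androgen-Regulated Glycoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free glycoproteomic dose-response studies of
    androgen-treated prostate cancer cells and clinical prostate tissue.
    Implements spike-in (BSA) normalization of protein intensity tables,
    post-search PSM score filtering, ternary direction coding of dose
    responses against a vehicle baseline with the 27-theoretical-pattern
    framework and selection of supraphysiologic-androgen-associated
    patterns, seeded K-means clustering of standardized profiles with
    cluster-to-pattern matching, hypergeometric overrepresentation analysis
    with Benjamini-Hochberg FDR control, Pearson-distance complete-linkage
    hierarchical clustering with Newick export, group contrasts and
    candidate biomarker triage combining cell-line dose patterns with
    tissue-cohort fold changes, and a seeded synthetic-data generator that
    emulates the statistical structure of such studies for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    fgsea,
    rlang,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
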