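Package: sh2ascan
Title: Short-H2A Histone Variant Reactivation Screening in Tumor
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to screen bulk tumor transcriptomes for aberrant
    (re)activation of the short histone H2A variants (H2A.B paralogues
    H2AFB1/H2AFB2/H2AFB3), and to characterize its downstream
    correlates. Implements TPM-threshold reactivation classification,
    trimmed-mean-of-M-values (TMM) expression normalization restricted
    to coding genes, Mann-Whitney U differential expression with exact
    and tie-corrected normal approximations, paralogue concordance and
    cross-cancer common gene sets, a composite cancer-testis antigen
    (CTA) Z-score, class-resolved differential splicing on
    percent-spliced-in (Psi) tables, somatic histone-mutation collation
    from MAF-like tables, and alignment-based mapping of oncohistone
    features onto variant sequences. A synthetic TCGA-like cohort
    generator with recorded ground truth makes the whole pipeline
    testable without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
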