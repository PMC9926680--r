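Package: kidneyCES
Title: Clinical Exome Variant Triage and Diagnostic Yield for Pediatric Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested implementation of a clinical exome sequencing
    (CES) diagnostic workflow for pediatric kidney disease: rare-variant
    filtering (population frequency, variant allele fraction, read depth,
    consequence), restriction to macro-category gene panels with escalation to
    a "kidneyome" super-panel, ACMG evidence combination into classes C1-C5,
    trio-based segregation analysis (de novo detection, compound-heterozygote
    phasing, mode-of-inheritance assessment), a read-depth CNV caller against
    a panel-of-normals baseline, per-patient report classification into
    conclusive / uncertain / inconclusive outcomes, and cohort-level
    diagnostic-yield statistics. Includes a fully synthetic cohort generator
    with a ground-truth ledger and a deterministic 191-patient demonstration
    cohort.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
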