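Package: rptriage
Title: Gene-Panel Variant Triage and Diagnostic Yield Analysis for
    Retinitis Pigmentosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable molecular-diagnostic workflow for targeted gene-panel
    sequencing of inherited retinal dystrophies such as retinitis pigmentosa.
    Provides capture coverage quality control (median target coverage,
    evenness score, poor-target flagging), high-quality variant designation
    from read support, a six-rule variant prioritization cascade with
    second-allele rescue for recessive genes, a three-axis rule-based
    pathogenicity classifier (in silico tool votes, evolutionary
    conservation, dual-cohort allele frequencies), pedigree segregation and
    de novo analysis with marker-based Mendelian consistency checks, and
    cohort-level diagnostic yield statistics.  A deterministic synthetic
    cohort generator plants causal genotypes under recessive, dominant,
    X-linked and de novo scenarios so that the whole pipeline can be
    exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
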