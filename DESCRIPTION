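Package: cilioscreen
Title: Variant Interpretation for NGS-Based Expanded Carrier Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a variant-interpretation workflow for expanded
    carrier screening of recessive disease genes, developed around a
    118-gene ciliopathy panel. Annotated variant calls are filtered with
    rule-based quality cut-offs and a linear support-vector-machine call
    classifier, then assigned to interpretation tiers (pathogenic, novel
    loss-of-function, "strong" variant of uncertain significance) by an
    ordered rule set combining population allele frequency, ClinVar and
    HGMD assertions, and an in-silico predictor ensemble vote. Strong VUS
    are prioritized for functional follow-up with a per-gene missense
    score and structure-based deleteriousness categories. Cohort-level
    reporting covers carrier frequencies, per-individual variant burden,
    variant recurrence, trio-based cis/trans phase inference, couples at
    reproductive risk, and observed versus Hardy-Weinberg-expected carrier
    frequencies. A synthetic-cohort generator with a deterministic
    benchmark fixture makes every stage testable without access to
    protected sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
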