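Package: dppscreen
Title: In Silico Proteolysis and Virtual Screening of DPP-IV Inhibitory Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for discovering dipeptidyl peptidase IV
    (DPP-IV) inhibitory peptides from food proteins. Implements rule-based
    in silico proteolysis with configurable protease specificities and
    missed cleavages, the BIOPEP-style frequency-of-release statistic
    (A and sum-A) for ranking enzyme combinations, physicochemical and
    positional sequence profiling of peptide sets, a multi-stage virtual
    screening funnel (bioactivity and toxicity thresholds, dipeptide
    scorecard scoring, sequence-characteristic rules, table-driven ADME
    filtering) with a per-peptide provenance ledger, quantification of
    plate-based inhibition and viability assays with four-parameter
    logistic IC50 fitting, and seeded synthetic-data generators for every
    input so the whole analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
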