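Package: abca4findex
Title: Functional Index Scoring and ACMG-AMP Classification of ABCA4 Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns replicate expression and ATPase assay measurements of
    ABCA4 missense variants into a functional index (F = E x S, the product
    of relative expression and relative substrate-stimulated ATPase
    activity), assigns a functional-severity category, derives ACMG-AMP
    evidence codes (PS3/BS3 from the F-index, PP3/BP4 from REVEL and
    SpliceAI, PM2 from gnomAD, PM5 from same-residue ClinVar records), and
    combines computed and externally supplied codes into the five-tier
    classification using a categorical rule table with a points-based
    conflict-resolution step. Ships a synthetic assay-replicate generator
    and a bundled case study of ten ABCA4 missense variants so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
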