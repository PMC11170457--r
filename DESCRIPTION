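Package: actijive
Title: Integrative JIVE Modeling of Accelerometry-Derived Sleep, Activity
    and Circadian Rhythm Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts sleep, physical-activity and circadian-rhythm feature
    blocks from minute-epoch wrist-accelerometry, decomposes the three blocks
    with a Joint and Individual Variation Explained (JIVE) low-rank model, and
    regresses a binary depression phenotype on the orthogonal JIVE subject
    scores.  Includes a two-tier synthetic-cohort generator (feature-level
    planted factor structure and minute-level epoch streams with planted
    sleep, bout and cosinor parameters) so that every pipeline stage can be
    validated against ground truth, plus a config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
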