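Package: semioloc
Title: Probabilistic Localizing Values of Seizure Semiologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives probabilistic localizing values of epileptic seizure
    semiologies from patient-level literature data. Maps free-text semiology
    descriptions onto a fixed category inventory with negation and
    string-similarity safeguards, encodes localizations over a hierarchical
    brain-region tree with interlobar-junction redistribution, normalizes
    multi-one-hot allocations so that each single-patient semiology sums to
    one, and mitigates temporal-lobe publication bias by filtering studies
    that preselected patients on known seizure foci. Reports conditional
    probabilities p(region | semiology) with bootstrap confidence intervals,
    an estimated unbiased prior distribution of localizations, and relative
    odds ratios from weighted two-by-two contingency tables. Includes a
    seeded synthetic cohort generator with known ground truth so that the
    entire pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
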