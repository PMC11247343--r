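Package: faerssignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on spontaneous
    adverse-event report databases structured like the FDA Adverse Event
    Reporting System (FAERS). Parses the quarterly "$"-delimited ASCII
    tables (DEMO/DRUG/REAC/OUTC) or an equivalent tab-separated dialect,
    deduplicates case versions, computes reporting odds ratios (ROR) with
    95% confidence intervals on 2x2 contingency tables per drug-event pair,
    screens signals against the classical a >= 3 and lower-CI > 1 criteria,
    extracts primary-suspect cases for enrolled preferred terms, and
    produces descriptive summaries (clinical characteristics, outcome
    severity, yearly trends) with Pearson chi-square comparisons. A
    seedable synthetic report generator with planted drug-event
    enrichments supports end-to-end testing without access to the live
    database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
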