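Package: cdssaudit
Title: Auditing Black-Box Treatment-Advice Systems Against Executable
    Clinical Guidelines
Version: 0.1.0
Authors@R: person("cdssaudit", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A test harness for systematically auditing a black-box clinical
    decision support system (CDSS) against an executable guideline ruleset.
    Clinical guideline logic is represented as declarative decision trees;
    synthetic patient cases are enumerated from decision points (full
    factorial or deduplicated by recommendation path); guideline and advisor
    recommendations are obtained per case, scored for concordance with a
    configurable cross-tabulation matrix (per-treatment scores -2..+2), and
    summed to an overall case score. Cases where the advisor recommends or
    suggests chemotherapy that the guideline marks not indicated receive red
    or orange safety flags (red takes precedence). Ships an executable
    encoding of the Dutch guideline for adjuvant treatment of stage I-III
    colon cancer, a perturbable mock advisor standing in for proprietary
    systems, recorded-advice adapters, per-stage aggregation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
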