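Package: faersvigil
Title: Pharmacovigilance Signal Detection for Checkpoint-Inhibitor Arrhythmias from FAERS-Style Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse-event
    reports in the FDA Adverse Event Reporting System (FAERS) quarterly ASCII
    format, focused on immune-checkpoint-inhibitor (ICI) associated arrhythmias.
    Parses and deduplicates multi-table quarterly extracts, normalises drug
    names against a bundled brand/generic dictionary, selects cases by a flat
    MedDRA preferred-term catalogue, classifies ICI regimens, and screens
    drug-event pairs with the reporting odds ratio (ROR), proportional
    reporting ratio (PRR) with Yates chi-square, and the Bayesian information
    component (IC) with gamma-posterior credible bounds, combined under a
    composite signal criterion. Includes time-to-onset and case-fatality
    analyses, a synthetic FAERS generator with planted disproportionality for
    end-to-end validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
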