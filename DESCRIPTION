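Package: fuzzydea
Title: Fuzzy FMEA and DEA Cross-Efficiency Risk Scoring for Pharmaceutical Supply Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for prioritising drug-shortage risks in a pharmaceutical
    supply network. Expert Occurrence-Severity-Detection (O-S-D) ratings of
    failure modes are fuzzified by single-input Mamdani fuzzy inference
    systems and defuzzified to smallest/middle/largest-of-maximum triples;
    each (firm, failure mode) pair then becomes a decision-making unit whose
    nine-value fuzzy profile is scored by input-oriented constant-returns
    DEA cross-efficiency against lower and upper anchor units. Low
    cross-efficiency means high risk; scores are mapped to linguistic risk
    levels and aggregated per firm, per supply-chain node and for the whole
    chain. Ships the published six-firm Malaysian case-study fixture, a
    seeded synthetic survey generator, tidy accessors and ggplot2 displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
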