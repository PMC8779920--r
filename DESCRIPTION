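Package: levipbpk
Title: Physiologically Based Pharmacokinetic Modelling and Virtual
    Bioequivalence for Levetiracetam
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-body perfusion-limited physiologically based
    pharmacokinetic (PBPK) simulation of levetiracetam coupled to a
    compartmental absorption and transit model of the gastrointestinal
    tract.  Provides Berezhkovskiy tissue-to-plasma partitioning, adult
    and pediatric (Chinese) physiologies, virtual populations,
    non-compartmental analysis, two one-sided-test bioequivalence
    statistics, a virtual crossover bioequivalence trial engine for
    rapidly dissolving tablet formulations, and pediatric regimen design
    against a therapeutic window, including missed-dose remediation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
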