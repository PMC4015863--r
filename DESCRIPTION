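Package: fivestep
Title: Five-Step Assessment of Statistical and Clinical Significance in
    Randomised Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging statistical and clinical significance of a
    randomised clinical superiority trial with a five-step procedure: exact
    confidence-interval and P-value reporting on the analysis scale; a
    Gaussian likelihood-ratio Bayes factor comparing the null hypothesis with
    the intervention effect hypothesised in the sample-size calculation
    (including a sceptical variant); adjustment of significance thresholds
    when a trial stopped early or performed interim analyses, via
    O'Brien-Fleming-type group-sequential boundaries; strong-control
    multiplicity adjustment across outcome comparisons (Bonferroni, Hommel,
    fixed-sequence, fallback); and clinical-significance assessment through
    risk differences, number-needed-to-treat/harm and a minimal clinically
    relevant difference.  Trials are described in a small JSON (or YAML)
    specification document; an orchestrator runs all five steps and renders
    machine-readable and human-readable reports.  A simulation module
    generates synthetic two-arm trials for calibration of type-I error,
    power, familywise error and Bayes-factor operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
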