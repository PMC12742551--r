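Package: ionpsqa
Title: Patient-Specific Quality Assurance for Scanned Ion Beams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing patient-specific quality
    assurance (PSQA) of scanned proton, helium and carbon ion beams with a
    water phantom and a 24-chamber ionization-chamber stack. Provides a
    synthetic spread-out Bragg peak dose engine, a chamber measurement model
    with configurable uncertainty sources, gradient-based chamber
    deactivation, normalized deviation scoring against institutional
    tolerance limits, rule engines for adapted-plan and data-integrity
    checks, seeded cohort generators, and the cohort-level statistical
    analysis (one-sample tests, variance-gated two-sample tests, ANOVA with
    Tukey post hoc, correlations, threshold sensitivity and time
    accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
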