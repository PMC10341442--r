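Package: rbcspectra
Title: Hemoglobin Derivative Unmixing and Storage Kinetics for Red Blood Cell Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies oxyhemoglobin, deoxyhemoglobin and methemoglobin in stored
    red-blood-cell suspensions from visible absorbance spectra (500-700 nm) by
    sign-constrained multicomponent Beer-Lambert fitting with a constant plus
    Rayleigh (lambda^-4) scattering baseline. Derives hemolysis percentages from
    paired supernatant/suspension fits, fits Normal-CDF transition kinetics to
    deoxyhemoglobin time courses (transition time and formation rate), and
    evaluates a quadratic oxidant/antioxidant balance model of reactive-oxygen-
    species production with its analytic optimal oxygen level. Includes a
    seeded synthetic-data generator so every stage is testable by parameter
    recovery, and a command-line interface for the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
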