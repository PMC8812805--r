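Package: thalscreen
Title: MALDI-TOF Haemoglobin Chain Quantification and Thalassaemia Screening
Version: 0.1.0
Authors@R: person("thalscreen", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Quantifies intact alpha-, beta- and gamma-globin chains from
    linear-mode MALDI-TOF blood spectra using a myoglobin internal standard
    (one-point m/z recalibration, 3000 ppm peak matching, internal-standard
    normalisation), derives ten chain-imbalance screening features (per-charge
    normalised intensities plus alpha/beta ratios and alpha-beta differences),
    and trains and evaluates eight binary classifier families for thalassaemia
    screening with rank-based ROC AUC, DeLong confidence intervals and full
    confusion-matrix metrics. Includes a seeded synthetic-cohort generator
    (Gaussian peaks at 1+ and 2+ charge states, exponential baseline, noise,
    calibration drift, linked clinical covariates) so the whole pipeline is
    testable without patient spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    FNN,
    quadprog
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
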