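Package: indexbias
Title: Index Event Bias Adjustment and Simulation for Case-Only Survival GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing and correcting index event (collider) bias in
    genome-wide association studies of disease survival conducted among cases.
    Reads and harmonizes two-trait GWAS summary statistics, estimates the bias
    slope relating case-only survival effects to disease risk effects by
    ordinary, inverse-variance-weighted and dilution-corrected (CWLS) least
    squares with regression diagnostics, and adjusts target-SNP hazard ratios.
    Includes a simulation engine for case-ascertained survival under a logistic
    incidence model with a latent confounder and Weibull survival times, with
    Cox estimation of the induced bias and back-calculation of the true hazard
    ratio implied by an observed one, plus a synthetic summary-statistics
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
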