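Package: ffakin
Title: Free Fatty Acid Kinetics Modelling for Insulin-Modified FSIGT Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling plasma free fatty acid (FFA) kinetics during
    an insulin-modified frequently sampled intravenous glucose tolerance test
    (FSIGT). Implements a one-compartment non-linear FFA model in which a
    remote insulin-action compartment suppresses lipolysis and plasma glucose
    proportionally controls FFA disposal, yielding an adipose-tissue insulin
    sensitivity index. Parameters are estimated by weighted non-linear least
    squares with fractional-standard-deviation identifiability diagnostics
    and residual-based model acceptance checks. Includes the Bergman glucose
    minimal model for comparison indices (insulin sensitivity, glucose
    effectiveness, acute insulin response, disposition index), a seeded
    synthetic FSIGT cohort generator with known ground truth, and cohort-level
    summaries and rank-correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
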