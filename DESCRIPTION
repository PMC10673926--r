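Package: indilife
Title: Individuality Analysis for Clonal Fish Life-History Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify among-individual differences (individuality)
    in behavior, growth, and reproduction from longitudinal experiments on
    clonal fish reared in standardized environments. Converts high-resolution
    position trajectories into daily activity and feeding-time measures; fits
    random-intercept linear mixed models by profiled restricted maximum
    likelihood and estimates raw and adjusted repeatabilities with
    parametric-simulation confidence intervals; fits individual von
    Bertalanffy growth curves; models reproductive profiles including the
    offspring size-number trade-off; and chains the stages into
    behavior-growth-reproduction linkage models selected by stepwise-backward
    likelihood-ratio tests. A configurable synthetic cohort generator makes
    every stage testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
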