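Package: oxival
Title: Agreement and Validation Statistics for Tissue Oximeters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for validating near-infrared spectroscopy
    (NIRS) tissue oximeters against weighted co-oximetry blood references in
    controlled hypoxia studies.  Computes the venous/arterial weighted
    reference saturation, standard and repeated-measures Bland-Altman
    agreement, per-subject Deming errors-in-variables regression with
    jackknife standard errors and meta-analytic pooling, random-coefficients
    mixed models, concordance correlation coefficients for clustered data,
    subject-block and double (moving-block) bootstrap model validation, a
    venous:arterial ratio uncertainty sweep, and a simulation-based precision
    power analysis.  Includes a synthetic hypoxia-plateau study generator for
    testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    metafor
Config/testthat/edition: 3
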