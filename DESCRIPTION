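Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization from GWAS
    summary statistics: instrument selection and LD clumping, allele
    harmonization with palindromic-variant filtering, five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode), sensitivity diagnostics (Cochran's Q,
    Egger intercept, leave-one-out, F-statistic instrument strength),
    binary-outcome power calculations, and a seeded generator of
    synthetic summary statistics for operating-characteristic studies.
    Ships a worked example on plasma homocysteine and intracranial
    aneurysm risk with eleven genetic instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
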