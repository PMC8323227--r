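Package: bimr
Title: Bi-Directional Two-Sample Mendelian Randomization from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for bi-directional two-sample Mendelian randomization
    (MR) with GWAS summary statistics: reading and validating summary-stat
    tables, instrument selection with LD-proxy substitution and allele
    harmonization, a battery of causal estimators (random-effects IVW,
    MR-Egger, weighted median, mode-based estimation, MR-PRESSO, robust
    MM regression, and a robust adjusted profile score) with heterogeneity
    and pleiotropy diagnostics, multivariable MR, binary-outcome power and
    minimum-detectable-odds-ratio inversion, DerSimonian-Laird
    random-effects meta-analysis with Egger's publication-bias test, and a
    calibrated synthetic summary-statistics generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
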