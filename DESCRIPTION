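Package: neoconcord
Title: Dual-Source Concordance of Neonatal Critical Conditions in
    Claims and Birth Certificates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring agreement between administrative
    claims data and birth-certificate records on neonatal critical
    conditions (NICU admission, respiratory distress syndrome,
    neonatal seizures, assisted ventilation, birth injury).
    Implements two-step deterministic mother-infant record linkage,
    claims-based phenotyping from ICD-9-CM and CPT code sets within a
    postnatal window, per-condition 2x2 concordance tables with
    Cohen's kappa, cross-source sensitivities and prevalence, a
    synthetic claims/birth-certificate cohort generator with known
    latent truth for validation, and fixtures reproducing the printed
    concordance statistics of a published Florida/Texas
    Medicaid-birth-certificate linkage study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
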