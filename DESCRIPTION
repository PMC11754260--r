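Package: pvsignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Signal", "Mining Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pharmacovigilance pipeline for FAERS-style quarterly
    ASCII extracts (DEMO, DRUG, REAC): case deduplication by caseid with
    latest-version retention, dictionary-based drug-name standardization,
    MedDRA PT/SOC event coding with a device-use term merge, 2x2 contingency
    construction at PT and SOC level (overall, stratified, and by calendar
    year), and the three classical disproportionality statistics - reporting
    odds ratio (ROR), proportional reporting ratio (PRR) with chi-square, and
    the Bayesian confidence propagation neural network information component
    (IC, EIC, VIC, IC025) - with their conventional signal thresholds.
    Includes a synthetic FAERS generator with known ground truth (injected
    relative risks, case versioning, demographic strata) so the full workflow
    and its statistical properties are testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
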