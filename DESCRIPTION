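Package: dustrisk
Title: Source Apportionment and Probabilistic Health-Risk Assessment for
    Flame Retardants in Vehicle Dust
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing organophosphate ester (OPE) and
    polybrominated diphenyl ether (PBDE) concentrations in vehicle dust:
    censored-data handling with half-MDL substitution, Spearman correlation
    and varimax-rotated principal component analysis with KMO and Bartlett
    diagnostics, uncertainty-weighted positive matrix factorization for
    source apportionment, three-route average-daily-dose exposure modelling
    (ingestion, dermal, inhalation), hazard-quotient/hazard-index and
    carcinogenic-risk characterization, and seeded Monte Carlo uncertainty
    propagation with contribution-to-variance sensitivity analysis. Includes
    a synthetic-data generator with planted source-factor structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
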