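Package: hetgwis
Title: Heteroscedastic Mixed-Model Scans for Gene-by-Smoking Interaction
    on Longitudinal Lung Function
Version: 0.1.0
Authors@R:
    person("hetgwis", "maintainers", email = "hetgwis@example.org",
           role = c("aut", "cre"))
Description: Genome-wide gene-by-smoking interaction analysis of
    longitudinal spirometry (FEV1) with linear mixed models that allow
    stratum-specific residual covariance by smoking status.  Implements a
    two-phase scan: a summed 3-degree-of-freedom likelihood-ratio
    filtering test computed from never-smoker and ever-smoker strata, and
    a pooled heteroscedastic testing step with Wald and F tests of SNP
    main and interaction effects.  Includes AIC-driven selection of
    smoking codings and covariance structures, genetic-relationship-matrix
    principal components, exact Hardy-Weinberg testing, genomic-control
    inflation diagnostics, one-tailed replication testing, and a
    synthetic-cohort generator emulating longitudinal and cross-sectional
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
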