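Package: allotrace
Title: Longitudinal T-Cell Receptor Repertoire Analysis for Transplant Cohorts
Version: 0.1.0
Authors@R: person("Repertoire", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of bulk TCR-beta clonotype repertoires from
    longitudinally sampled kidney-transplant recipients. Reads MiXCR-style
    clonotype exports, resolves CD4/CD8 sorting ambiguity, normalizes
    sequencing depth by repeated downsampling without replacement, defines
    donor-reactive clonotypes from a pre-transplant mixed-lymphocyte-reaction
    (MLR) pair by fold expansion, and tracks them through post-transplant
    repertoires. Provides repertoire diversity metrics (clonality, R20),
    Jensen-Shannon divergence for clone- and VJ-usage turnover, annotation of
    virus-specific clonotypes against a VDJdb-style table, and the cohort
    inferential layer (t-tests, mixed factorial ANOVA with Greenhouse-Geisser
    correction). Includes a synthetic-cohort generator with programmed ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
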