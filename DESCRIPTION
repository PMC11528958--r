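Package: psnet
Title: Patient-Sharing Networks of Health Care Professionals from
    Visit-Level Registries
Version: 0.1.0
Authors@R:
    person("psnet", "developers", email = "psnet@example.org", role = c("aut", "cre"))
Description: Builds patient-sharing networks among health care
    professionals from visit-level primary care registry data.  Implements
    the full analysis pipeline: cohort identification for mental-health and
    substance-use patients with configurable diagnosis-code rules, visit and
    patient exclusion cascades with audit reports, bipartite
    patient-professional graph construction and thresholded one-mode
    projection, descriptive network statistics (degree, density, geodesic
    distance, transitivity, betweenness, and occupation-group relative
    centralities), size-matched resampling null distributions with
    Wilcoxon and sign tests, and dyad-independent exponential random graph
    models (ERGMs) with occupation and municipality main effects and
    uniform or differential homophily, fitted by the exact dyadic
    likelihood, with simulation-based goodness-of-fit.  A synthetic
    registry generator emulates the statistical structure of such data for
    testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
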