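Package: carenet
Title: Social Network Analysis of Clinical Secure-Messaging Metadata
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds directed, weighted communication networks between
    healthcare providers from secure text-messaging metadata linked to
    inpatient hospital encounters, and analyses them in three stages: a
    global provider network, encounter-level subnetworks restricted to
    messages sent before a clinical deterioration (Time 0, the activation
    of a rapid response or code team), and 12-hour epoch subnetworks
    anchored at Time 0.  Provides from-scratch normalized centrality
    measures (betweenness, closeness, eigenvector), network topology
    summaries (density, eccentricity, diameter, radius, global clustering
    coefficient), nonparametric group comparisons (Mann-Whitney U,
    Kruskal-Wallis, Bonferroni, chi-square/Fisher), cohort accounting,
    role-flow aggregation, and a seeded synthetic message-log generator
    that reproduces the statistical structure the analysis assumes, so the
    full pipeline is testable without access to protected hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
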