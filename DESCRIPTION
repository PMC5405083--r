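Package: fcmst
Title: Functional Connectivity Networks and Spanning-Tree Descriptors for
    ROI Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional-connectivity graphs from regional
    (ROI) BOLD time-series, quantifies small-world organization against
    edge- and weight-preserving random null ensembles, extracts
    maximum-weight spanning trees with Kruskal's algorithm and computes
    their local (degree, betweenness, eccentricity) and global (diameter,
    radius, leaf fraction, tree hierarchy, degree divergence, degree
    correlation) descriptors, detects hub regions from per-subject argmax
    fractions, correlates nodal metrics with median response times, and
    runs FDR-corrected unbalanced one-way ANOVA group comparisons.
    Includes a synthetic-cohort generator with controllable modular
    correlation structure, planted hubs, and planted metric-response-time
    correlations, so the full pipeline is testable without access to
    restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
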