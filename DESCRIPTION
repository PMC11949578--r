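Package: dfcstates
Title: Two-State Dynamic Functional Connectivity and Its Test-Retest Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis
    with a two-state model: windowed Fisher-z connectivity from ROI time
    series, cosine-distance k-means clustering of state instances with
    back-projection and optional within-subject centering, state-dynamics
    parameters (mean dwell time, prevalence, intertransition interval,
    state variability), test-retest reliability via one-way random-effects
    intraclass correlation with bootstrap confidence intervals, and
    graph-theoretic characterization of state centroids (weighted
    modularity, global efficiency).  Includes a synthetic two-session
    cohort generator with Markov switching between an integrated and a
    segregated covariance regime so every pipeline stage can be validated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
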