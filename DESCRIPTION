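Package: cclpp
Title: Sparse Canonical Correlation Analysis with Locality Preserving
    Projection for Multimodal Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of functional and structural brain connectomes
    for two-group infant cohorts. Builds per-subject Pearson-correlation
    (functional) and fiber-count (structural) connectivity matrices over a
    common cortical parcellation, screens edges with a two-sample t-test,
    and fits a sparse canonical correlation analysis with a locality
    preserving projection (graph-Laplacian) penalty that discriminates the
    two groups while regressing the canonical scores onto preterm birth
    age. Includes post-hoc characterization of the identified connections
    (Euclidean length classes, hemispheric type, resting-state-network
    co-occurrence, cortical folding classes, activation-area overlap), a
    synthetic cohort generator with planted cross-modal signal for
    validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
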