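Package: traceassign
Title: Geographic Assignment of Birds from Trace-Element Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns migratory birds to natal origin from bone
    trace-element profiles. Provides calcium-ratio normalization and
    z-scoring, one-way MANOVA (Wilks' lambda with Rao's F approximation),
    stepwise canonical discriminant analysis with leave-one-out
    cross-validation and Press's Q, centroid-ratio assignment of unknown
    birds with immigrant/unassigned detection, agglomerative hierarchical
    clustering with multiscale-bootstrap AU/BP cluster support, and a
    synthetic multi-site generator for validating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
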