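Package: vfspace
Title: Vector-Space Modelling of Word Production in Verbal Fluency Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the tuple-basis vector-space model of semantic
    network connectivity and verbal fluency (VF) word production. Builds
    the 2^i tensor-product basis of item tuples with bitstring and decimal
    encodings and barcode renderings, represents normalized activation
    state vectors, constructs orthogonal word-production rotation
    operators from a single 2x2 minimal matrix, tests tensor-product
    separability of states, implements the fused Bousfieldian time-course
    function with its exponential, hyperbolic and logarithmic special
    cases and the geometric word-retrieval probability law, fits
    time-course models to timestamped production records with
    small-sample-corrected information-criterion model selection, and
    simulates verbal-fluency-like production records by stochastic
    sampling with replacement over the tuple structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
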