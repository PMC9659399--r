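Package: gaexpr
Title: Genetic-Algorithm Evolution and Analysis of Facial Expression Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for evolving facial-expression blendshape vectors with an
    interactive genetic algorithm driven by simulated observers, and for the
    statistics defined on the evolved expressions: GA stochastic-noise
    thresholds and cosine-distance exceedance, principal component analysis
    with Gaussian-mixture clustering and emotion confusion matrices,
    per-emotion blendshape fingerprints with FACS action-unit labels,
    support-vector-machine category prediction, and a permutation test of
    emotion-recognition performance binned by cosine distance to the
    perceiver's preferred expression. Human participants are replaced by
    parameterized observer models, so the full analysis stack runs offline
    on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
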