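Package: toothSSM
Title: Statistical Shape Modelling of Teeth with Surface Material Labels
Version: 0.1.0
Authors@R:
    person("toothSSM", "Developers", email = "toothssm@example.org",
           role = c("aut", "cre"))
Description: A point-distribution statistical shape modelling (SSM) pipeline
    for triangulated tooth surface meshes carrying a binary enamel/dentin
    surface label. Provides mesh I/O (PLY, STL, OFF) and geometric
    primitives, a parametric generator of canine-like tooth populations
    with known modes of variation, rigid pre-alignment (bounding-box
    scaling, centroid alignment, iterative closest point), elastic
    mesh-to-mesh registration establishing dense correspondence,
    correlation-method principal component analysis over combined
    geometry and material variables, synthetic instance generation and
    sigma sweeps, cemento-enamel junction (CEJ) extraction from material
    labels, automated anatomical landmarking and measurement, and the
    accompanying validation statistics (Bland-Altman agreement, linear
    regression of measurements on PC weights, one-way ANOVA with Tukey
    HSD post-hoc comparison of PC scores between groups).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
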