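Package: langmuir
Title: Langmuir Monolayer Isotherms, Curve Projection, and Interfacial Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Langmuir-monolayer membrane models: surface
    pressure-area isotherm mechanics (adjacent-average smoothing,
    compressional modulus, two-dimensional phase classification, limiting
    area, collapse pressure and scalar parameter tables), comparison of
    whole curve families by Fastmap-initialised IDMAP multidimensional
    projection with silhouette scoring, and interfacial observables for
    slab particle systems (density profiles, Gibbs dividing surface,
    pressure-tensor surface tension, radial distribution functions and
    potentials of mean force). Includes seeded synthetic-data generators
    for isotherm families across membrane models and subphase additive
    concentrations, toy particle configurations and pressure-tensor
    profiles with analytically known observables, and an end-to-end
    reproducible pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
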