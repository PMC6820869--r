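Package: sashier
Title: Hierarchical Unified-Fit Analysis of Small-Angle Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-level Unified (Guinier/power-law) modelling of
    one-dimensional small-angle neutron and X-ray scattering profiles from
    hierarchically organised materials such as enzyme-graphene biosensor
    matrices. Fits N-level Unified scattering models by weighted least
    squares, separates the fitted total intensity into per-level curves with
    propagated experimental uncertainties, demagnifies upper structural
    levels onto the monomer length scale, derives degrees of aggregation,
    volume ratios, packing fractions and fractal resistivity exponents,
    inverts intensities to pair-distance distributions by direct and
    regularised indirect Fourier transforms, and reconstructs low-resolution
    dummy-bead shapes by simulated annealing against the Debye scattering
    formula, including normalized-spatial-discrepancy comparison and model
    averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    Rcpp,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
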