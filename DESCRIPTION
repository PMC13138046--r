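Package: fibrilkit
Title: Quantitative Analysis of Collagen I Fibrillogenesis Kinetics and
    Fibril Network Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how nanoparticles such as extracellular
    vesicles modulate collagen I self-assembly. Segments oscillatory-shear
    gelation curves (storage modulus versus time) into nucleation, growth
    and plateau phases with a derivative-threshold rule; summarises endpoint
    frequency sweeps; extracts fibril content, mesh size (exponential fit to
    the inter-fibril gap-length distribution), network connectivity and
    branch lengths from confocal reflectance z-stacks via per-slice
    binarization and skeletonization; measures pseudo-3D particle-to-fibril
    and particle-to-junction distances with a 500 nm association rule;
    converts pseudo-2D particle counts to volumetric concentrations; and
    provides the matching statistical comparisons (Welch's t, one- and
    two-way ANOVA with Tukey-Kramer post hoc tests, Pearson dose-response).
    A seeded synthetic-data generator produces sigmoidal gelation curves and
    isotropic line-process fibril stacks with known ground truth so that
    every estimator is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    car,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
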