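Package: pdlhyper
Title: Fiber-Fraction-Weighted Hyperelastic Model of the Human Periodontal Ligament
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transversely isotropic hyperelastic constitutive modelling of the
    human periodontal ligament (PDL) under incompressible uniaxial tension.
    Implements a two-phase exponential strain-energy function in which the
    collagen-fiber contribution is weighted by the fiber volume fraction
    measured on stained sections, the closed-form uniaxial Cauchy stress with
    its incompressibility pressure term, an independent tensor-pipeline and
    finite-difference verification of the closed form, constrained
    Levenberg-Marquardt parameter estimation from stress-stretch curves with
    goodness-of-fit reporting, fiber area-fraction computation from segmented
    masks or pixel counts, and seeded generators for synthetic tensile curves
    and fiber masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff
Config/testthat/edition: 3
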