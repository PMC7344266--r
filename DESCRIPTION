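Package: fofmoc
Title: First-Order Uncertainty Propagation for Ocean-Color Bio-Optical
    Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Propagates radiometric uncertainty in spectral remote-sensing
    reflectance through standard ocean-color bio-optical algorithms
    (blended chlorophyll-a, diffuse attenuation at 490 nm, particulate
    organic carbon, normalized fluorescence line height, and a
    semi-analytical inherent-optical-property inversion) using the
    first-order first-moment (GUM) law of propagation of uncertainty,
    with and without spectral covariance. Analytic gradients are verified
    against central differences and a Monte-Carlo perturbation engine.
    Includes model-misfit uncertainty estimation for the reflectance
    inversion, measurement-uncertainty budgets combining data and model
    components for particulate organic carbon, and a synthetic multiband
    reflectance generator emulating oligotrophic to mesotrophic waters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
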