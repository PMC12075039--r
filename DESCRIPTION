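Package: chelamorph
Title: Geometric Morphometrics and Sensillar Mapping of Decapod Chelae
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heterochely and sexual dimorphism in
    decapod (hermit-crab) claws from landmark and sensilla-coordinate data:
    TPS landmark input/output, generalised Procrustes analysis, canonical
    variate analysis with permutation inference, Goodall's F and Procrustes
    ANOVA, single-linkage classification of sensillar articulation sites
    (S1-S4), absolute and area-weighted sensillar density statistics,
    standardised frequency-map rasters, and linear mixed-effects models with
    Satterthwaite degrees of freedom.  Includes a seeded synthetic-population
    generator emulating the study design so every stage is testable without
    the original specimens, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
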