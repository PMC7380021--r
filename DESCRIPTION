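Package: artevol
Title: Eco-Evolutionary Dynamics of Alternative Reproductive Tactics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sex, two-morph stage-structured population model for species
    with discrete alternative reproductive tactics (armed fighters versus
    unarmed scramblers), parameterized for the bulb mite Rhizoglyphus robini.
    The model couples a hawk-dove mating game to density-dependent demography
    and extends it with intraspecific killing by fighters. An adaptive-dynamics
    toolkit iterates the nonlinear projection map to its population-dynamic
    equilibrium, computes mutant invasion fitness against the resident
    environment, builds pairwise invasibility plots, locates and classifies
    evolutionarily singular strategies of the fighter fraction (including
    evolutionary bistability), and runs one- and two-parameter sweeps with
    isocline extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
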