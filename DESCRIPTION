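Package: dermadiff
Title: Combined Diffusion and Adsorption Modelling of Nanoparticle
    Transport Through Layered Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of passive nanoparticle transport
    through layered barriers such as woven filter membranes and the
    brick-and-mortar stratum corneum. Computes Stokes-Einstein diffusivities
    and Stokes sedimentation velocities, inverts steady-state Fick's-law
    Franz-cell measurements to effective diffusivities and retardation
    coefficients, fits a modified Langmuir retention law a = 1/(1 + k*Y) to
    (surface parameter, retardation) observations, and predicts permeated
    nanoparticle mass versus barrier depth together with penetration limits.
    Includes a synthetic Franz-cell experiment generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
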