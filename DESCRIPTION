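Package: zincleft
Title: Zinc Release, Diffusion and Uptake Dynamics in the Synaptic Cleft
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the dynamics of vesicularly released solutes (notably
    Zn2+) in a disc-shaped synaptic cleft. Provides closed-form stationary
    radial concentration profiles with a buffered effective diffusion
    coefficient, Bessel-eigenmode relaxation time constants, a first-order
    approximate space-time solution, a conservative finite-volume simulator
    with pulsed vesicular release and saturable transmembrane uptake, a
    vesicle ion-budget calculator, and a forward/inverse fluorescence
    indicator calibration model with a seeded global fitting procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
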