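Package: uhdrchem
Title: Stochastic Reaction-Diffusion Simulation of Water Radiolysis at Ultra-High Dose Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Step-by-step (SBS) Brownian-dynamics simulation of the radiation
    chemistry of liquid water under sequential proton irradiation at dose rates
    spanning conventional (0.02 Gy/s) to ultra-high / FLASH (500 Gy/s)
    conditions. Radiolysis species are tracked as point particles in a
    micrometre-scale water phantom; second-order reactions use
    Green's-function diffusion-equation (GFDE) encounter probabilities,
    dissolved oxygen is treated as a continuum scavenger with
    pseudo-first-order kinetics, and boundaries are reflective. A parametric
    spur surrogate converts proton traversals into 1-ps species placements.
    Scored observables are radiation chemical yields (G values) and their dose
    rate dependence, ensemble statistics, and oxygen depletion per unit dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
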