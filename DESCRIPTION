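Package: dpiaero
Title: Surface Energetics, Aerodynamic Assessment and Stochastic Lung
    Deposition for Carrier-Based Dry Powder Inhalers
Version: 0.1.0
Authors@R:
    person("DPI", "Maintainers", email = "maintainers@dpiaero.org",
           role = c("aut", "cre"))
Description: Analysis chain for carrier-based dry powder inhaler (DPI)
    formulation studies. Inverts two-probe-liquid contact angles to
    dispersive and polar surface-energy components via the Wu
    harmonic-mean system and derives interparticle-interaction metrics
    (work of cohesion and adhesion, Derjaguin adhesion force, spreading
    coefficient); performs blend composition, capsule fill-mass and
    content-uniformity arithmetic with spectrophotometric LOD/LOQ
    gating; reduces Andersen cascade impactor runs to emitted fraction,
    fine particle fractions, MMAD and GSD by log-probit regression; and
    simulates whole-lung aerosol deposition with a stochastic Monte
    Carlo airway model including breath-hold and exhalation phases.
    Includes seeded synthetic-data generators for every input so the
    whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
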