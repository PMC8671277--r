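Package: lvadopt
Title: Intra-Cycle Optimal Pump-Speed Control for Left Ventricular Assist
    Devices with a Switched Atrioventricular-Plane-Displacement Heart Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter model of the left heart and systemic
    circulation in which ventricular pumping is driven by the longitudinal
    displacement of the atrioventricular plane (AVPD), coupled to an axial
    rotary blood pump (LVAD). The cardiac cycle is treated as a switched
    system with seven phases (atrial contraction, ventricular contraction,
    ejection, relaxation and filling, delimited by valve and contraction
    events). The package provides event-detecting forward simulation of
    periodic cycles, Radau direct-collocation transcription with
    switching-time scaling, model personalization by damped Gauss-Newton
    regression on measured left-ventricular pressure with Fisher-information
    uncertainty estimates, and computation of optimal pump-speed profiles in
    constant, continuous and piecewise-constant scenarios under physiological
    constraints (flow balance, periodicity, partial support, backflow limit,
    target cardiac output, suction prevention).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
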