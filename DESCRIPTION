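Package: swdcontrol
Title: Thalamocortical Neural Mass Modelling and Closed-Loop Abatement of
    Spike-and-Wave Discharges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a four-population thalamocortical
    neural mass model of absence epilepsy, together with closed-loop
    controllers that abate spike-and-wave discharges (SWD).  Provides a
    fixed-step fourth-order Runge-Kutta integrator with stochastic
    background noise and pulse-train disturbances, classification of
    dynamical regimes (tonic and clonic oscillations, low/high saturated
    steady states, m-spike SWD), dominant-frequency and extrema analysis,
    one- and two-parameter sweeps with multistability probing, equilibrium
    continuation with Hopf detection and fold-of-cycles (double cycle)
    localisation, sliding-mode and radial-basis-function adaptive tracking
    controllers with a low-pass-filtered switching term, a variance-based
    on-demand trigger, and reference EEG generators (model background state
    and a synthetic alpha-band surrogate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
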