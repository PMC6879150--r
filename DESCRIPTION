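Package: flowparse
Title: Competitive-Dynamics Model of Object Motion Perception During
    Self-Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a neural model of primate areas MT and MST that
    recovers world-relative object motion during observer translation.
    MSTd template populations (radial band-pass, speed-summating, speed
    gradient, and ground-plane units) estimate the global optic-flow
    pattern produced by self-motion through recurrent competitive
    dynamics, and feed back to suppress the matching direction, speed and
    disparity signals in MT-/MSTv object-motion populations. The package
    generates frontoparallel-plane, ground-plane and stereo-cloud
    stimuli with an embedded probe object, integrates the model with
    fixed-step Euler dynamics, decodes object direction by population
    vector, and reports angular shifts and flow-parsing gains comparable
    to published human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
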